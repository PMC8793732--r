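# Completeness-catalogue bookkeeping for published sauropod necks.

.CATEGORIES <- c("complete_described", "complete_undescribed",
                 "missing_atlas", "other_near_complete")

#' Load the bundled sauropod neck-completeness catalogue
#'
#' The 28 published complete and near-complete sauropod neck specimens, with
#' a completeness category for each: `complete_described` (complete,
#' articulated and adequately described), `complete_undescribed`,
#' `missing_atlas` (complete and articulated from C2) and
#' `other_near_complete`. "Complete" is used in the weak sense that at least
#' a good part of each vertebra is present. Clade labels and cervical counts
#' are curator-entered from published accounts.
#'
#' @param path optional path to a catalogue CSV in the same schema
#'   (`specimen_id,taxon,clade,category,cervical_count,described_in_english,notes`);
#'   defaults to the bundled catalogue.
#' @return data.frame of completeness records.
#' @export
load_catalogue <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "neck_catalogue.csv", package = "vertcol")
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(cervical_count = "integer",
                                        described_in_english = "logical"))
  bad <- setdiff(rec$category, .CATEGORIES)
  if (length(bad)) stop("unknown completeness category: ",
                        paste(bad, collapse = ", "))
  if (any(!is.na(rec$cervical_count) & rec$cervical_count < 1))
    stop("cervical_count must be >= 1 when present")
  rec
}

#' Summarize neck completeness by category and clade
#'
#' @param records data.frame of completeness records (see [load_catalogue]).
#' @return Object of class `completeness_summary`: list with `by_category`
#'   (named counts over all four categories, zeros included), `by_clade`
#'   (clade x category contingency table) and `total`.
#' @examples
#' completeness_summary(load_catalogue())$by_category
#' @export
completeness_summary <- function(records) {
  rec <- as.data.frame(records)
  if (nrow(rec)) {
    bad <- setdiff(rec$category, .CATEGORIES)
    if (length(bad)) stop("unknown completeness category: ",
                          paste(bad, collapse = ", "))
  }
  cat_f <- factor(if (nrow(rec)) rec$category else character(),
                  levels = .CATEGORIES)
  by_category <- table(category = cat_f)
  by_clade <- if (nrow(rec)) table(clade = rec$clade, category = cat_f)
              else table(clade = character(), category = cat_f)
  structure(list(by_category = by_category, by_clade = by_clade,
                 total = nrow(rec)),
            class = "completeness_summary")
}

#' @export
print.completeness_summary <- function(x, ...) {
  cat(sprintf("Neck completeness: %d specimens\n", x$total))
  print(x$by_category)
  cat("\nBy clade:\n")
  print(x$by_clade)
  invisible(x)
}

#' Known species per complete neck
#'
#' How many named species exist for each unambiguously complete neck — a
#' rarity statistic (e.g. 342 species against 9 complete necks gives "one in
#' 38 known species").
#'
#' @param n_species,n_complete positive integers.
#' @return `round(n_species / n_complete)`.
#' @examples
#' species_per_complete_neck(342, 9)  # 38
#' @export
species_per_complete_neck <- function(n_species, n_complete) {
  if (!is.numeric(n_species) || !is.numeric(n_complete) ||
      n_species < 1 || n_complete < 1)
    stop("counts must be positive integers")
  as.integer(round(n_species / n_complete))
}

#' Phylogenetic-bracket cervical count
#'
#' Two-taxon min-max bracket: if the two closest relatives with known necks
#' have the given cervical counts, the parsimonious range for the bracketed
#' taxon is their inclusive min-max range.
#'
#' @param count_a,count_b cervical counts (positive integers) of the
#'   bracketing taxa; order-free.
#' @return Integer vector `c(min, max)`.
#' @examples
#' bracket_cervical_count(13, 12)  # c(12, 13)
#' @export
bracket_cervical_count <- function(count_a, count_b) {
  if (!is.numeric(count_a) || !is.numeric(count_b) ||
      count_a < 1 || count_b < 1)
    stop("cervical counts must be positive integers")
  as.integer(c(min(count_a, count_b), max(count_a, count_b)))
}
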