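# Bundled data

All files are small plain-text CSV, UTF-8, "." decimal point.

- `table1.csv` — raw vertical/horizontal articular-facet extents for six measured
  cervical series (giraffe C2–C7, savannah monitor C3–C7, alligator C5–D2,
  ostrich C5–C11, *Diplodocus carnegii* CM 84 C2–C15, *Giraffatitan brancai*
  MB.R.2180 C2–C7). Units are arbitrary but consistent within a specimen
  (mm or image pixels). The alligator was measured on the anterior (procoelous)
  facet; the ostrich on maximum rather than midline extents. The alligator D1/D2
  rows carry serial indices 9/10, continuing the cervical numbering, because the
  measured run is treated as consecutive across the cervicodorsal junction.
  Provenance note: the source table heads the *Diplodocus* block "CM 82", an
  apparent slip for the holotype number CM 84 used everywhere else; the fixture
  uses CM 84.
- `table1_printed_rows.csv` — the 3-dp V/H, first-difference and first-ratio
  values as printed in the source table (display roundings of the raw data
  above; kept separate so recomputation can be checked cell by cell).
- `table1_printed_summary.csv` — the printed per-specimen summary cells.
  The `erratum` column flags cells that are internally inconsistent in the
  source: the *Diplodocus* max_ratio prints 1.139 although the printed
  first-ratio column for that specimen contains 1.361.
- `figure_pixels.csv` — pixel width/height of cotyles measured from published
  photographs (*Giraffatitan* C4 and C6; *Diplodocus* C13 and C14). These are
  width-first measurements and deliberately kept separate from `table1.csv`,
  whose *Diplodocus* C13/C14 values come from a different measurement set.
- `neck_catalogue.csv` — the 28 published complete and near-complete sauropod
  neck specimens with completeness categories (complete_described,
  complete_undescribed, missing_atlas, other_near_complete). Clade labels and
  cervical counts are curator-entered from the running text, not machine-read.
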