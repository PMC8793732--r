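specimen_id,taxon,clade,category,cervical_count,described_in_english,notes
CM 11338,Camarasaurus lentus,Camarasauridae,complete_described,12,TRUE,juvenile referred specimen
CM 3018,Apatosaurus louisae,Diplodocidae,complete_described,15,TRUE,holotype; C13-C15 badly crushed
CCG V 20401,Mamenchisaurus hochuanensis,Mamenchisauridae,complete_described,,FALSE,holotype; every vertebra sheared obliquely
ZDM T5402,Shunosaurus lii,Non-neosauropod Eusauropoda,complete_described,,FALSE,mature referred specimen; described in Chinese
BYU 9047,Cathetosaurus lewisi,Camarasauridae,complete_described,12,TRUE,holotype; C10-C12 severely damaged
MACN-N 15,Amargasaurus cazaui,Dicraeosauridae,complete_described,,TRUE,holotype; 22 articulated presacrals
ZDM 0083,Mamenchisaurus youngi,Mamenchisauridae,complete_described,,FALSE,holotype; described in Chinese
MUCPv-323,Futalognkosaurus dukei,Titanosauria,complete_described,,TRUE,holotype; neck in two articulated sections
SSV12001,Xinjiangtitan shanshanesis,Mamenchisauridae,complete_described,,TRUE,holotype
USNM 13786,Camarasaurus lentus,Camarasauridae,complete_undescribed,12,,subadult referred specimen; atlas preserved
MNBH TIG3,Jobaria tiguidensis,Non-neosauropod Eusauropoda,complete_undescribed,12,,holotype; articulated C-shaped neck
SMA 002,Camarasaurus sp.,Camarasauridae,complete_undescribed,,,near-perfect articulation
MAU-Pv-LI-595,La Invernada titanosaur,Titanosauria,complete_undescribed,,,entire preserved specimen articulated
MAU-Pv-AC-01,unnamed titanosaur,Titanosauria,complete_undescribed,,,articulated skull to last caudal
MB.R.4886,Dicraeosaurus hansemanni,Dicraeosauridae,missing_atlas,12,,holotype; complete C2-C12
PMU 233,Euhelopus zdanskyi,Somphospondyli,missing_atlas,17,TRUE,holotype (exemplar a)
ZDM T5401,Shunosaurus lii,Non-neosauropod Eusauropoda,missing_atlas,,FALSE,subadult holotype; atlas probably missing
MCT 1487-R,DGM Series A titanosaur,Titanosauria,missing_atlas,12,TRUE,12 cervicals except atlas with three proximal dorsals
GCP-CV-4229,Spinophorosaurus nigerensis,Non-neosauropod Eusauropoda,missing_atlas,13,TRUE,holotype; articulated C2-C13
MOZ-Pv1232,Lavocatisaurus agrioensis,Rebbachisauridae,other_near_complete,,TRUE,complete C1-C11 but possibly not to last cervical
YPM 1910,Camarasaurus lentus,Camarasauridae,other_near_complete,12,TRUE,holotype; complete from C2 or C3
SMA 0004,Kaatedocus siberi,Diplodocidae,other_near_complete,,TRUE,holotype; C3-C14 preserved
AODF 888,Diamantinasaurus sp.,Titanosauria,other_near_complete,,TRUE,preserved from C3 or C4
CM 84,Diplodocus carnegii,Diplodocidae,other_near_complete,15,TRUE,holotype; C2-C15 preserved but not all articulated
ZDM T5701,Omeisaurus tianfuensis,Mamenchisauridae,other_near_complete,,FALSE,holotype; neck unarticulated and missing about two elements
QJGPM 1001,Qijianglong guokr,Mamenchisauridae,other_near_complete,17,TRUE,holotype; C2-C11 articulated with C12-C17 associated
MNBH TIG9,Jobaria tiguidensis,Non-neosauropod Eusauropoda,other_near_complete,,TRUE,partially articulated axis through mid-dorsals
MNBH TIG6,Jobaria tiguidensis,Non-neosauropod Eusauropoda,other_near_complete,,,subadult; articulated C2-C11
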