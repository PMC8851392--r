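subject_id,group,sex,age,mmse,injected_dose,caa_status,css_pattern,overlap_pct
CAA01,CAA,M,74,28,291.15,probable,disseminated,0
CAA02,CAA,M,79,14,302.37,probable,disseminated,81
CAA03,CAA,M,79,20,294.00,possible,focal,100
CAA04,CAA,F,75,6,303.00,probable,disseminated,21
CAA05,CAA,F,70,26,280.00,possible,focal,75
CAA06,CAA,M,85,29,299.00,probable,disseminated,73
CAA07,CAA,M,71,26,288.34,probable,disseminated,52
CAA08,CAA,F,45,21,295.77,probable,disseminated,69
CAA09,CAA,M,80,28,295.00,probable,focal,100
CAA10,CAA,F,75,28,299.00,possible,focal,0
HC01,HC,F,63,n.a.,293.00,n.a.,n.a.,n.a.
HC02,HC,M,60,n.a.,309.00,n.a.,n.a.,n.a.
HC03,HC,M,66,n.a.,299.00,n.a.,n.a.,n.a.
HC04,HC,M,58,n.a.,315.00,n.a.,n.a.,n.a.
HC05,HC,F,65,n.a.,315.00,n.a.,n.a.,n.a.
HC06,HC,M,65,n.a.,301.00,n.a.,n.a.,n.a.
HC07,HC,F,69,n.a.,326.00,n.a.,n.a.,n.a.
HC08,HC,M,70,n.a.,297.00,n.a.,n.a.,n.a.
HC09,HC,F,66,n.a.,271.00,n.a.,n.a.,n.a.
HC10,HC,M,66,n.a.,293.00,n.a.,n.a.,n.a.
HC11,HC,F,64,n.a.,352.00,n.a.,n.a.,n.a.
HC12,HC,M,72,n.a.,322.00,n.a.,n.a.,n.a.
HC13,HC,F,59,n.a.,288.00,n.a.,n.a.,n.a.
HC14,HC,M,80,n.a.,295.00,n.a.,n.a.,n.a.
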