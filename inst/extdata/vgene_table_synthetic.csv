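locus,v_gene,cdr1_aa,cdr2_aa,pseudogene
alpha,TRAVS1,FIRPW,GTIWQRAN,FALSE
alpha,TRAVS2,YFPDSD,EEMDPHWD,FALSE
alpha,TRAVS3,HSCSAAY,HKHFMV,FALSE
alpha,TRAVS4,NRTMATV,RFLWPARH,FALSE
alpha,TRAVS5,MSLNID,LVVVAQCV,FALSE
alpha,TRAVS6,SYWAPCM,NSIGHSYK,FALSE
alpha,TRAVS7,EEGNWET,DAYEPK,FALSE
alpha,TRAVS8,CPNTTNV,WFCSYMN,FALSE
alpha,TRAVS9,WWHRVQ,MWVYCH,FALSE
alpha,TRAVS10,GVWTRSL,HLNDEQV,FALSE
alpha,TRAVS11,WGEHFV,HRWPTWM,FALSE
alpha,TRAVS12,VWTFLG,FHMGCA,FALSE
alpha,TRAVS13,,,TRUE
alpha,TRAVS14,,,TRUE
beta,TRBVS1,QGWRMM,ANYNM,FALSE
beta,TRBVS2,SAQSD,KHELN,FALSE
beta,TRBVS3,APQFKI,KTYSNE,FALSE
beta,TRBVS4,CHFDV,HCSFLW,FALSE
beta,TRBVS5,TERYV,SNVCFC,FALSE
beta,TRBVS6,LFSQV,HYQDAV,FALSE
beta,TRBVS7,GSNRR,DRPMP,FALSE
beta,TRBVS8,IWTSNM,HAYKKI,FALSE
beta,TRBVS9,THKLFT,PPKPVY,FALSE
beta,TRBVS10,ESWCES,MHGDSW,FALSE
beta,TRBVS11,SPTQHC,LQRLL,FALSE
beta,TRBVS12,WMDFK,HKAMM,FALSE
beta,TRBVS13,,,TRUE
beta,TRBVS14,,,TRUE
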