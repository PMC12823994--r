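sample_name,age,sex,cmv_status,productive_templates,productive_rearrangements,top10_templates,top100_templates,top1000_templates
REP-001,25.9,male,positive,1455733,917533,2900,29000,289639
REP-002,36.3,female,positive,977210,546566,2460,24600,245946
REP-003,66,male,negative,470504,267609,1340,13400,133669
REP-004,33.5,male,negative,332876,216059,650,6500,64429
REP-005,32.1,male,negative,588172,405439,840,8400,83638
REP-006,38.2,female,negative,865225,618691,1450,14500,144721
REP-007,34.4,male,positive,774689,415981,2040,20400,203621
REP-008,42.3,female,positive,1140771,670940,2900,29000,289275
REP-009,53,male,negative,419314,226112,1300,13000,129410
REP-010,64.8,male,negative,480721,295364,1390,13874,138074
REP-011,42.1,male,positive,733371,494249,1620,16200,161996
REP-012,26.9,male,positive,1186604,681103,3060,30600,305318
REP-013,34.5,female,positive,897903,692083,950,9471,94071
REP-014,32.8,female,negative,604088,446902,590,5900,58571
REP-015,50.3,female,positive,566579,357141,1130,11300,112474
REP-016,43.5,female,positive,804677,472146,2330,23300,232393
REP-017,63.3,male,positive,674140,309069,2540,25400,253452
REP-018,51.2,female,positive,772640,483042,2000,20000,199353
REP-019,22.3,male,negative,766734,507357,1090,10900,108608
REP-020,40.2,female,positive,490592,287024,1030,10300,102969
REP-021,57.3,female,positive,545238,290131,1690,16900,168292
REP-022,46.8,female,positive,961955,633376,1600,16000,159652
REP-023,53,female,positive,735655,427821,1670,16700,166437
REP-024,34.8,male,negative,546163,344825,650,6500,64310
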