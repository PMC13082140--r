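zip,income
10001,21846
10002,28246
10003,31047
10004,33186
10005,34972
10006,36536
10007,37945
10008,39240
10009,40447
10010,41585
10011,42665
10012,43699
10013,44694
10014,45655
10015,46588
10016,47496
10017,48382
10018,49251
10019,50103
10020,50941
10021,51766
10022,52581
10023,53386
10024,54183
10025,54973
10026,55757
10027,56536
10028,57311
10029,58083
10030,58851
10031,59618
10032,60383
10033,61148
10034,61912
10035,62678
10036,63444
10037,64211
10038,64981
10039,65754
10040,66530
10041,67309
10042,68093
10043,68881
10044,69675
10045,70475
10046,71280
10047,72093
10048,72913
10049,73741
10050,83272
10051,75424
10052,76280
10053,77146
10054,78024
10055,78914
10056,79816
10057,80732
10058,81662
10059,82608
10060,83570
10061,84549
10062,85546
10063,86563
10064,87601
10065,88661
10066,89745
10067,90854
10068,91990
10069,93155
10070,94351
10071,95580
10072,96845
10073,98148
10074,99493
10075,100883
10076,102322
10077,103814
10078,105364
10079,106978
10080,108662
10081,110423
10082,112269
10083,114212
10084,116261
10085,118432
10086,120740
10087,123207
10088,125857
10089,128721
10090,131840
10091,135267
10092,139070
10093,143348
10094,148240
10095,153957
10096,160841
10097,169499
10098,181177
10099,199144
10100,250000
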