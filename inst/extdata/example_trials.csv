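trial_id,ma_id,sr_id,outcome_role,non_english,data_level,arm1_mean,arm1_sd,arm1_n,arm2_mean,arm2_sd,arm2_n,smd,smd_se
t1_01,ma1,sr1,primary,yes,arm,0.36251782041602,0.980323897713926,49,-0.686661957967231,0.789121305504594,19,,
t1_02,ma1,sr1,primary,yes,arm,0.399842840062804,1.09158185968528,38,0.0415544495946447,1.07474647940642,47,,
t1_03,ma1,sr1,primary,no,arm,0.738913603157736,1.17406646414183,37,-0.0504435576283957,1.12684617931569,53,,
t2_01,ma2,sr2,primary,no,arm,-0.55078883984759,0.869291695486866,40,0.0261955576998974,0.941642488608478,50,,
t2_02,ma2,sr2,primary,no,arm,-0.271167334085261,1.09794357331854,20,0.0757469974485191,1.05319774730281,59,,
t2_03,ma2,sr2,primary,yes,arm,0.540404734299748,1.04856156407195,20,0.187047701406399,1.06881715404215,56,,
t2_04,ma2,sr2,primary,no,arm,0.0264141073846393,0.804371896747734,16,-0.151650877629681,0.892589676973604,23,,
t2_05,ma2,sr2,primary,yes,arm,-0.0798364183806785,1.05100525205763,17,0.198635889184,0.864540706442166,43,,
t2_06,ma2,sr2,primary,yes,arm,0.129480662903537,1.00057443439917,35,0.0658652352392028,1.2788784196494,26,,
t2_07,ma2,sr2,primary,no,arm,0.701207992229956,0.810464512096771,16,0.178102326588509,1.13256054653163,34,,
t3_01,ma3,sr3,primary,no,arm,0.575528894621774,0.978177002016803,52,0.191985177922733,1.13451057343891,23,,
t3_02,ma3,sr3,primary,no,arm,-0.0218613227438844,0.846449176037884,24,0.0954826452218764,0.896236902084834,57,,
t3_03,ma3,sr3,primary,yes,arm,-0.462086223093282,0.969430626854494,54,-0.149016991223979,0.98558462887019,49,,
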