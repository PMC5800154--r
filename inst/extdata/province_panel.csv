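region,year,gender,cases,n
Jiangsu,1991,all,134,1255
Jiangsu,1993,all,164,1213
Jiangsu,1997,all,530,1443
Jiangsu,2000,all,302,1277
Jiangsu,2004,all,350,1186
Jiangsu,2006,all,426,1131
Jiangsu,2009,all,491,1255
Jiangsu,2011,all,435,1178
Shandong,1991,all,249,1195
Shandong,1993,all,234,1092
Shandong,1997,all,532,1380
Shandong,2000,all,345,1146
Shandong,2004,all,361,1111
Shandong,2006,all,336,1131
Shandong,2009,all,377,1142
Shandong,2011,all,388,1084
Henan,1991,all,166,1124
Henan,1993,all,192,1036
Henan,1997,all,599,1498
Henan,2000,all,303,1127
Henan,2004,all,564,1338
Henan,2006,all,500,1191
Henan,2009,all,489,1239
Henan,2011,all,488,1183
Hubei,1991,all,188,1269
Hubei,1993,all,229,1191
Hubei,1997,all,555,1513
Hubei,2000,all,231,1167
Hubei,2004,all,347,1146
Hubei,2006,all,375,1049
Hubei,2009,all,377,1068
Hubei,2011,all,356,1015
Hunan,1991,all,193,1259
Hunan,1993,all,155,1211
Hunan,1997,all,443,1405
Hunan,2000,all,290,1184
Hunan,2004,all,265,1142
Hunan,2006,all,242,1224
Hunan,2009,all,341,1196
Hunan,2011,all,317,1131
Guangxi,1991,all,172,1362
Guangxi,1993,all,173,1359
Guangxi,1997,all,619,1688
Guangxi,2000,all,201,1264
Guangxi,2004,all,353,1356
Guangxi,2006,all,293,1316
Guangxi,2009,all,471,1443
Guangxi,2011,all,380,1431
Guizhou,1991,all,168,1549
Guizhou,1993,all,180,1367
Guizhou,1997,all,424,1687
Guizhou,2000,all,204,1299
Guizhou,2004,all,232,1216
Guizhou,2006,all,223,1181
Guizhou,2009,all,315,1138
Guizhou,2011,all,258,1079
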