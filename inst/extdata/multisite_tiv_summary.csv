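procedure_id,mri_model,vendor,protocol,n,icc21,icc21_nonsmall,etiv_mean,etiv_sd,sbtiv_mean,sbtiv_sd,deviation_mean,deviation_sd,abs_error_mean,abs_error_sd
Overall,,,,6524,0.78,0.79,1576865,173438,1580168,159199,-3303,109866,83434,71548
A,Prisma,Siemens,HARP,208,0.73,0.75,1599380,162141,1581799,158767,17581,116702,94987,69740
B,Prisma,Siemens,HARP,96,0.73,0.73,1549394,164337,1555976,174440,-6582,125453,91578,85483
C,Prisma,Siemens,HARP,39,0.82,0.82,1641860,128342,1647789,143599,-5929,82903,63079,53154
D,Prisma,Siemens,HARP,79,0.79,0.80,1633306,167183,1658247,175458,-24941,109412,89861,66502
E,Prisma fit,Siemens,HARP,32,0.77,0.82,1577572,176220,1605332,170213,-27760,116868,88318,80012
F,Prisma fit,Siemens,HARP,50,0.84,0.84,1626801,154359,1611529,167832,15272,92102,75890,53330
G,Skyra,Siemens,HARP,34,0.72,0.72,1616763,198540,1513506,222343,103257,132621,152223,68554
H,Skyra,Siemens,HARP,131,0.78,0.75,1592787,174094,1529599,176943,63188,103534,99121,69587
I,Skyra fit,Siemens,HARP,98,0.72,0.70,1620943,152804,1550964,157049,69979,101270,98687,73236
J,Skyra fit,Siemens,HARP,290,0.80,0.80,1620575,162942,1648909,175098,-28334,103407,82662,68132
K,Skyra fit,Siemens,HARP,994,0.82,0.82,1593172,170531,1592131,162480,1041,101035,80026,61632
L,Tim Trio,Siemens,HARP,79,0.73,0.73,1568459,131214,1519499,142006,48960,91965,91455,49135
M,Verio Dot,Siemens,HARP,63,0.74,0.74,1660226,144733,1595649,173555,64577,102829,101171,66413
N,Verio,Siemens,HARP,65,0.80,0.82,1595594,151787,1562263,173617,33331,98692,82306,63153
O,Verio,Siemens,HARP,122,0.83,0.84,1574865,196048,1552656,204050,22209,113820,92755,69122
P,Verio,Siemens,HARP,15,0.80,0.80,1572121,135841,1547831,152855,24289,91294,77976,49520
Q,MR750,GE,HARP,16,0.93,0.93,1466800,118347,1489148,113967,-22348,40354,36430,27305
R,MR750,GE,HARP,15,0.82,0.82,1543656,181127,1466053,134828,77603,67997,89691,49566
S,Premier,GE,HARP,15,0.89,0.89,1542204,141395,1549570,115785,-7366,62639,50756,34952
T,Prisma,Siemens,CRHD,109,0.79,0.79,1600890,189146,1596955,171844,3935,117098,92566,71272
U,Prisma,Siemens,CRHD,1662,0.77,0.77,1609330,169901,1580947,157191,28383,108742,90955,65978
V,Prisma,Siemens,SRPB_iso,185,0.94,0.94,1576305,133584,1583218,142064,-6913,46257,34676,31286
W,Verio Dot,Siemens,SRPB_iso,195,0.92,0.93,1544601,147316,1551515,135287,-6915,55010,40857,37367
X,Verio Dot,Siemens,SRPB_iso,109,0.90,0.90,1601287,142648,1591055,131903,10231,61200,45667,41788
Y,Verio,Siemens,SRPB_iso,241,0.91,0.89,1665306,156320,1677009,146352,-11703,64376,49734,42404
Z,Signa HDxt,GE,SRPB_iso,129,0.87,0.87,1550860,128219,1588599,128343,-37739,56262,52621,42545
AA,Tim Trio,Siemens,SRPB_aniso,226,0.62,0.67,1482482,220790,1595149,145683,-112667,135817,125138,124368
AB,Spectra,Siemens,SRPB_aniso,71,0.78,0.78,1494227,143588,1583119,140009,-88893,54344,90884,50894
AC,MR750w,GE,SRPB_aniso,434,0.66,0.65,1481221,148512,1597353,152177,-116131,81169,116309,80913
AD,Achieva,Philips,SRPB_aniso,722,0.74,0.85,1503445,170190,1508724,120239,-5278,105619,68589,80450
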