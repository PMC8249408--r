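cell_id,x_um,y_um,phenotype,tissue_category
ca000001,234.1224126,260.3919056,cancer,cancer_island
ca000002,288.1361576,256.5356045,cancer,cancer_island
ca000003,320.9777306,238.4067245,cancer,cancer_island
ca000004,254.9382935,224.2172813,cancer,cancer_island
ca000005,298.8333544,219.7874939,cancer,cancer_island
ca000006,289.6040898,271.9352477,cancer,cancer_island
ca000007,271.54672,234.8886212,cancer,cancer_island
ca000008,301.7461075,239.7798013,cancer,cancer_island
ca000009,265.7400464,233.1053236,cancer,cancer_island
ca000010,243.8560658,250.7655909,cancer,cancer_island
ca000011,279.4620056,267.0925775,cancer,cancer_island
ca000012,246.2498606,240.4060345,cancer,cancer_island
ca000013,272.1661396,223.4891813,cancer,cancer_island
ca000014,239.3351183,247.9817434,cancer,cancer_island
ca000015,255.8774713,253.3900419,cancer,cancer_island
ca000016,79.24457804,408.0790453,cancer,cancer_island
ca000017,64.11726583,396.990525,cancer,cancer_island
ca000018,54.86487733,407.6033405,cancer,cancer_island
ca000019,40.36351221,438.8057211,cancer,cancer_island
ca000020,70.58301566,386.2232037,cancer,cancer_island
ca000021,24.77550923,387.924756,cancer,cancer_island
ca000022,32.84995404,405.7866037,cancer,cancer_island
ca000023,19.04713849,424.6219786,cancer,cancer_island
ca000024,81.49587249,416.8064204,cancer,cancer_island
ca000025,24.38957287,370.0780161,cancer,cancer_island
ca000026,13.8617163,408.758128,cancer,cancer_island
ca000027,25.1774879,386.7860416,cancer,cancer_island
ca000028,33.8599658,369.841846,cancer,cancer_island
ca000029,78.55182466,375.0292813,cancer,cancer_island
ly000001,93.12775149,295.1814767,B,stroma
ly000002,316.3490611,204.2466078,T,stroma
ly000003,359.0579123,433.2144501,T,stroma
ly000004,270.903302,54.08045254,T,stroma
ly000005,102.3562992,160.9449682,T,stroma
ly000006,449.9944943,84.14366376,T,stroma
ly000007,61.79216458,25.78995819,T,stroma
ly000008,475.7734732,276.6407165,T,stroma
ly000009,390.857563,70.96057851,B,stroma
ly000010,481.0679824,79.44228733,T,stroma
ly000011,57.12596385,389.4045068,B,cancer_island
ly000012,488.7760696,221.874529,T,stroma
ly000013,310.2347509,65.76124986,T,stroma
ly000014,463.7136328,283.2223792,T,stroma
ly000015,101.1183565,386.9405688,T,stroma
ly000016,107.7645909,210.6070279,T,stroma
ly000017,460.9626114,30.4152912,T,stroma
ly000018,361.0577754,192.7232165,B,stroma
ly000019,380.8506941,231.2025576,B,stroma
ly000020,142.6387253,20.71191568,T,stroma
ly000021,171.8294404,205.3628266,T,stroma
ly000022,170.6967083,196.2655113,T,stroma
ly000023,393.9798984,321.1784392,T,stroma
ly000024,182.2499955,17.96794403,T,stroma
ly000025,332.5612776,46.52238323,B,stroma
ly000026,186.40588,437.7458235,T,stroma
ly000027,60.51043468,2.098987577,T,stroma
ly000028,415.4232601,78.92668608,T,stroma
ly000029,209.1586412,254.1189445,T,stroma
ly000030,41.01566772,279.4557511,T,stroma
ly000031,88.01379788,168.2206584,T,stroma
ly000032,90.48056859,349.1463932,B,stroma
ly000033,336.7137763,142.3649284,B,stroma
ly000034,303.49774,251.0843766,T,cancer_island
ly000035,129.7631531,320.761091,T,stroma
ly000036,263.0706705,125.4867595,B,stroma
ly000037,289.7156086,116.6481178,T,stroma
ly000038,263.0714835,137.7229376,T,stroma
ly000039,259.058327,133.3828956,T,stroma
ly000040,274.0739658,112.1218211,T,stroma
ly000041,283.1183767,142.5753769,T,stroma
ly000042,274.5154779,116.0725552,T,stroma
ly000043,267.0233068,117.2444713,T,stroma
ly000044,286.3844376,113.0461514,B,stroma
ly000045,289.5804115,133.7692801,T,stroma
ly000046,245.8507867,142.2238551,T,stroma
ly000047,280.1718133,151.0318748,T,stroma
ly000048,260.6870748,138.5937636,T,stroma
ly000049,275.2476242,143.713758,B,stroma
ly000050,247.1923622,142.8899161,T,stroma
ly000051,262.8298062,157.4129121,B,stroma
ly000052,255.8474613,168.5909812,T,stroma
ly000053,260.5329573,135.0150832,B,stroma
ly000054,254.6629473,164.7656912,T,stroma
ly000055,189.0763515,355.2094862,T,stroma
ly000056,197.5447572,336.2060726,T,stroma
ly000057,180.4436601,342.8609664,T,stroma
ly000058,262.3076155,205.7015873,B,cancer_island
ly000059,31.64526044,409.2781084,T,cancer_island
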