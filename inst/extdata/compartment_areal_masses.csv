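condition,neuron,element,compartment,am_ng_cm2,c_ppm,eps_pct
CTRL,N1,Fe,nucleus,10,200.9,14.0
CTRL,N1,Fe,nucleolus,14.3,286.3,13.3
CTRL,N1,Fe,cytoplasm,7.7,154.6,13.5
CTRL,N1,Fe,granules,11,NA,13.6
CTRL,N1,Ca,nucleus,1.2,24.5,16.7
CTRL,N1,Ca,nucleolus,1.5,29.4,13.3
CTRL,N1,Ca,cytoplasm,2.5,50.3,13.7
CTRL,N1,Ca,granules,2.8,NA,14.3
CTRL,N1,S,nucleus,59.2,1183.8,16.9
CTRL,N1,S,nucleolus,61.8,1235.7,16.8
CTRL,N1,S,cytoplasm,66.6,1332.7,16.9
CTRL,N1,S,granules,98.2,NA,16.9
CTRL,N1,P,nucleus,79,1579.4,20.6
CTRL,N1,P,nucleolus,97.9,1958.9,20.7
CTRL,N1,P,cytoplasm,112.8,2256.3,20.7
CTRL,N1,P,granules,86,NA,20.7
CTRL,N2,Fe,nucleus,9.8,196.9,13.3
CTRL,N2,Fe,nucleolus,19.6,391.8,13.3
CTRL,N2,Fe,cytoplasm,7.6,152.5,13.5
CTRL,N2,Fe,granules,10.6,NA,13.2
CTRL,N2,Ca,nucleus,1.2,24.6,16.7
CTRL,N2,Ca,nucleolus,1.9,38.3,15.8
CTRL,N2,Ca,cytoplasm,2.5,49.2,13.6
CTRL,N2,Ca,granules,2.7,NA,14.8
CTRL,N2,S,nucleus,60.7,1213.1,16.8
CTRL,N2,S,nucleolus,78.9,1577.1,16.9
CTRL,N2,S,cytoplasm,72.3,1447,16.9
CTRL,N2,S,granules,107.3,NA,16.9
CTRL,N2,P,nucleus,78,1559.5,20.6
CTRL,N2,P,nucleolus,155.1,3102.4,20.7
CTRL,N2,P,cytoplasm,100.9,2018.7,20.7
CTRL,N2,P,granules,78.3,NA,20.7
ASYN,N1,Fe,nucleus,8.9,178.6,13.5
ASYN,N1,Fe,nucleolus,14.3,285.6,13.3
ASYN,N1,Fe,cytoplasm,8.5,169.1,13.5
ASYN,N1,Fe,granules,22.9,NA,13.5
ASYN,N1,Ca,nucleus,1.1,22,18.2
ASYN,N1,Ca,nucleolus,1.9,37.6,15.8
ASYN,N1,Ca,cytoplasm,2.2,43.2,13.7
ASYN,N1,Ca,granules,2.6,NA,15.4
ASYN,N1,S,nucleus,47.9,957.3,16.9
ASYN,N1,S,nucleolus,58.2,1164,16.8
ASYN,N1,S,cytoplasm,60.7,1214.7,16.9
ASYN,N1,S,granules,66.1,NA,16.9
ASYN,N1,P,nucleus,72.8,1455.7,20.7
ASYN,N1,P,nucleolus,106.6,2131.8,20.7
ASYN,N1,P,cytoplasm,97.4,1948.9,20.7
ASYN,N1,P,granules,85.5,NA,20.7
ASYN,N2,Fe,nucleus,8.7,173.4,13.8
ASYN,N2,Fe,nucleolus,13.6,272.5,13.2
ASYN,N2,Fe,cytoplasm,8.8,175.4,13.5
ASYN,N2,Fe,granules,23.3,NA,13.3
ASYN,N2,Ca,nucleus,1.1,21.2,9.1
ASYN,N2,Ca,nucleolus,1.7,34.4,11.8
ASYN,N2,Ca,cytoplasm,1.9,38.9,13.6
ASYN,N2,Ca,granules,2.4,NA,12.5
ASYN,N2,S,nucleus,52.9,1058,16.8
ASYN,N2,S,nucleolus,69,1380.7,17.0
ASYN,N2,S,cytoplasm,62.7,1254.1,16.9
ASYN,N2,S,granules,72.9,NA,16.9
ASYN,N2,P,nucleus,74.6,1492.1,20.6
ASYN,N2,P,nucleolus,141.6,2831.9,20.7
ASYN,N2,P,cytoplasm,117.4,2347.6,20.7
ASYN,N2,P,granules,96.2,NA,20.7
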