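"residue","CpHMD","PROPKA","DeepKa","PB_A","H++","KaML-CBT","KaML-ESM"
"E2","3.600","5.237","4.400","5.543","3.615","4.026","1.788"
"D97","3.000","4.566","4.313","5.404","4.079","2.647","1.169"
"D107","1.500","2.433","2.855","3.503","3.256","0.495","0.306"
"D113","2.600","2.566","3.512","3.484","4.403","1.303","2.471"
"D121","1.300","0.311","1.442","0.748","2.505","0.176","2.282"
"E117","5.000","3.410","4.321","3.210","5.174","4.452","6.741"
"D172","3.200","1.580","1.943","0.814","2.281","3.424","5.076"
"E233","4.400","3.330","3.016","2.273","2.717","5.316","5.739"
"D330","2.900","2.764","1.885","1.795","1.057","4.180","3.221"
"D12","3.400","4.246","3.118","3.712","2.057","4.585","2.589"
"D21","2.800","4.326","3.352","4.418","2.439","3.465","1.147"
"D43","3.900","5.558","5.088","6.244","4.650","3.807","1.998"
"D54","2.200","3.396","3.598","4.429","3.792","1.382","0.730"
"D74","3.100","3.405","4.207","4.416","4.964","1.851","2.590"
"D82","4.100","3.405","4.519","4.030","5.567","2.867","4.732"
"D92","1.900","0.454","1.481","0.470","2.444","1.126","3.448"
"D137","2.500","0.821","1.393","0.222","1.927","2.462","4.409"
"D149","3.700","2.390","2.302","1.391","2.215","4.411","5.285"
"D183","4.600","4.129","3.412","3.087","2.735","5.806","5.294"
"D195","2.000","2.536","1.448","1.826","0.424","3.269","1.553"
"D224","3.300","4.651","3.582","4.527","2.578","4.176","1.873"
"D268","2.400","4.082","3.415","4.588","2.790","2.570","0.504"
"D283","4.000","5.410","5.384","6.365","5.363","3.402","2.315"
"D315","1.700","2.332","2.957","3.394","3.547","0.549","0.830"
"E9","3.800","3.428","4.479","4.216","5.469","2.509","4.057"
"E29","4.900","3.657","4.758","3.888","5.793","3.931","6.191"
"E48","2.700","1.032","1.788","0.624","2.496","2.401","4.563"
"E139","3.500","2.004","2.145","1.103","2.273","3.978","5.267"
"E244","4.300","3.513","2.987","2.442","2.489","5.383","5.337"
"E274","5.200","5.404","4.400","4.547","3.455","6.501","5.136"
"E301","4.700","5.822","4.700","5.486","3.646","5.752","3.557"
"D37","< 1","4.9","3","0.3","2.9","3.1","3.3"
"E62","< 1","2.5","2.6","0.4","< 0","3.4","3.7"
"E71","< 1","1.1","4.1","0.5","4.6","3.6","3.9"
"D126","< 1","3.2","2.5","0.5","< 0","3.0","3.4"
"D127","> 8","7.4","5.5","3.8","6.6","4.8","4.6"
"D256","> 8","6","3.2","0.6","< 0","4.1","4.3"
"E296","> 8","9.6","7.3","8.9","9.4","6.9","6.2"
"D312","> 8","4.5","6.5","1.5","4.0","4.4","4.8"
"D158","2.1","2.6","2.3","0.9","< 0","2.4","2.0"
"E181","3.9","3.3","3.6","2.2","< 0","3.8","4.2"
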