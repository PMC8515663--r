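channel,J,bic_traj,aic_traj
depression,2,-2534.8,-2530.7
depression,3,-2403.8,-2397.2
depression,4,-2363.7,-2354.7
depression,5,-2365.3,-2353.8
anxiety,2,-1525.8,-1521.7
anxiety,3,-1484.2,-1477.6
anxiety,4,-1476.3,-1467.2
anxiety,5,-1489.8,-1478.3
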