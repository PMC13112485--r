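algorithm,cluster,healthy,tumor
rdbpso,pred_healthy,389,60
rdbpso,pred_tumor,19,332
standard_pso,pred_healthy,387,65
standard_pso,pred_tumor,21,327
gmm,pred_healthy,288,60
gmm,pred_tumor,120,332
kmeans,pred_healthy,244,54
kmeans,pred_tumor,164,338
hierarchical,pred_healthy,166,47
hierarchical,pred_tumor,242,345
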