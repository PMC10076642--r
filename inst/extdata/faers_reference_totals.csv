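drug,total_reports,group,published_ror,published_ci_low,published_ci_high
secukinumab,44688,IBD,2.13,1.96,2.30
secukinumab,44688,colitis,1.60,1.43,1.79
ixekizumab,24406,IBD,2.79,2.39,3.27
ixekizumab,24406,colitis,1.96,1.56,2.47
brodalumab,1796,IBD,1.48,0.48,4.6
brodalumab,1796,colitis,NA,NA,NA
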