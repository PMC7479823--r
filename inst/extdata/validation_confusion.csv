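predicted,pseudoprogression,pr_sd,true_pd
good,3,3,3
poor,0,1,6
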