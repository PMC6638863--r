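# Prior distributions for the ten radiative parameters (shared by all PFTs).
# family: uniform (p1 = lower, p2 = upper) or lognormal (p1 = log-mean,
# p2 = log-sd, natural-log scale).
name,family,p1,p2
cf,uniform,0.4,0.98
of,uniform,-0.5,0.5
LT_PAR,lognormal,-2.9176,0.6729
LR_PAR,lognormal,-2.5367,0.3748
LT_NIR,lognormal,-1.241,0.2588
LR_NIR,lognormal,-1.3402,0.2096
WT_PAR,uniform,0.001,0.005
WR_PAR,uniform,0.05,0.25
WT_NIR,uniform,0.001,0.005
WR_NIR,uniform,0.1,0.5
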