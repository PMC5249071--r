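snp_id	risk_allele_freq	odds_ratio
snp_001	0.4914	1.0503
snp_002	0.1038	1.0535
snp_003	0.2841	1.0734
snp_004	0.3862	1.0509
snp_005	0.3453	1.0901
snp_006	0.2237	1.0587
snp_007	0.0694	1.0885
snp_008	0.4400	1.0497
snp_009	0.4418	1.0878
snp_010	0.4898	1.0565
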