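id	tpm_wt	tpm_mt	printed_fold_change
csi-novel-01	2.8	0.0	NA
csi-novel-02	4.5	3.3	1.4
csi-novel-03	220.1	1248.5	5.7
csi-novel-04	8.9	0.0	NA
csi-novel-05	90.5	29.6	3.1
csi-novel-06	11.2	1.5	7.5
csi-novel-07	12.3	4.8	2.6
csi-novel-08	287.1	369.1	1.3
csi-novel-09	0.0	2.7	NA
csi-novel-10	27.9	4.5	6.2
csi-novel-11	591.5	132.7	4.5
csi-novel-12	15.1	4.5	3.4
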