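# Hand-derived outcome of the default filter (qual > 20, supporting reads > 4,
# depth < 100, MAF > 0.05, spacing >= 5 bp) applied to filter12.vcf.
# 10 diploid samples -> 20 alleles per site; two 0/1 carriers give MAF = 0.10,
# a single 0/1 carrier gives MAF = 0.05 exactly (boundary, rejected).
pos	outcome	reason
100	kept	passes all rules
103	rejected	spacing: 3 bp from the kept SNP at 100 (earlier record wins)
200	rejected	qual = 20 exactly (strict > 20)
300	rejected	sample s03 has 4 supporting reads (strict > 4)
400	rejected	total depth = 100 exactly (strict < 100)
500	rejected	MAF = 1/20 = 0.05 exactly (strict > 0.05)
600	kept	passes all rules
700	kept	passes all rules
800	kept	passes all rules
900	kept	passes all rules
1000	kept	passes all rules
1100	kept	passes all rules
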