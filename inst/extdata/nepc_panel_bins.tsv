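fusion	GSE156289 NCI-H660	GSE154575 MSKCC-EF1	GSE118206 transformed prostate basal epithelial	GSE118206 small cell prostate cancer	GSE118206 prostate adenocarcinoma	GSE31528 bone metastases
ACYP2-SPTBN1	+	+	-	+	-	-
CTNND2-GNPDA1	+++	+	+	+++	-	-
SPSB4-PXYLP1	++	+	-	+	-	-
TMPRSS2-ERG	+++	-	-	++	-	+
RIPPLY2-CYB5R4	+	-	+++	++	-	-
FOXP1-PDCD6IP	+++	+++	-	+++	+	+++
SLC25A42-EEF2	+++	++	-	++	-	-
EEF2-SLC25A42	+++	+++	-	+++	-	+
DCAF7-DDX42	++	-	-	+	-	-
SNX13-ATP2C1	+++	-	+	+++	+++	+++
SKIV2L2-PLPP1	+++	+++	-	+++	-	+++
ANAPC13-VIT	+++	+++	-	+++	-	+
USP15-C12orf56	+++	+++	-	+++	-	-
ZNF420-TMLHE	+++	+++	-	+++	-	-
FXYD2-DSCAML1	-	-	-	-	-	-
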