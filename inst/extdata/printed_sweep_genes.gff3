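##gff-version 3
# The 18 sweep-candidate genes of the published two-group rice screen
# (RAP-DB identifiers; coordinates 1-based inclusive). The nSNP and ZHp
# attributes are the published per-gene values.
chr4	rapdb	gene	5161947	5167404	.	+	.	ID=Os04g0175600;description=Similar to 0-methyltransferase;nSNP=22;ZHp=-1.57
chr4	rapdb	gene	5178491	5186485	.	+	.	ID=Os04g0175900;description=Winged helix repressor domain;nSNP=36;ZHp=-1.59
chr4	rapdb	gene	5189974	5194492	.	-	.	ID=Os04g0176200;description=Similar to N-methyltransferase;nSNP=3;ZHp=-1.57
chr4	rapdb	gene	5210111	5216557	.	+	.	ID=Os04g0176300;description=Hypothetical protein;nSNP=48;ZHp=-1.57
chr4	rapdb	gene	5210122	5216551	.	-	.	ID=Os04g0176400;description=Similar to serine carboxypeptidase 1;nSNP=2;ZHp=-1.57
chr5	rapdb	gene	15866499	15866891	.	+	.	ID=Os05g0338933;description=Proton-dependent oligopeptide transport;nSNP=26;ZHp=-1.58
chr5	rapdb	gene	15873838	15880419	.	-	.	ID=Os05g0339000;description=VHS domain-containing protein;nSNP=8;ZHp=-1.58
chr5	rapdb	gene	15931964	15933657	.	-	.	ID=Os05g0340000;description=Conserved hypothetical protein;nSNP=4;ZHp=-1.49
chr10	rapdb	gene	4226902	4229142	.	+	.	ID=Os10g0162856;description=Chalcone and stilbene synthases;nSNP=30;ZHp=-1.52
chr10	rapdb	gene	5198971	5204584	.	+	.	ID=Os10g0174751;description=Hypothetical protein;nSNP=2;ZHp=-1.57
chr10	rapdb	gene	5236268	5237084	.	+	.	ID=Os10g0175500;description=Hypothetical gene;nSNP=43;ZHp=-1.59
chr10	rapdb	gene	5237690	5245182	.	-	.	ID=Os10g0175700;description=Hypothetical protein;nSNP=17;ZHp=-1.57
chr10	rapdb	gene	5247357	5248013	.	+	.	ID=Os10g0175800;description=Similar to nodulin protein;nSNP=10;ZHp=-1.57
chr10	rapdb	gene	6079970	6087844	.	-	.	ID=Os10g0188100;description=Conserved hypothetical protein;nSNP=2;ZHp=-1.55
chr10	rapdb	gene	6103102	6109882	.	-	.	ID=Os10g0188275;description=Hypothetical protein;nSNP=3;ZHp=-1.56
chr10	rapdb	gene	6104501	6110244	.	+	.	ID=Os10g0188300;description=Similar to JHL05D22.13 protein;nSNP=5;ZHp=-1.56
chr10	rapdb	gene	6111498	6115269	.	+	.	ID=Os10g0188400;description=Similar to ACI13;nSNP=10;ZHp=-1.56
chr10	rapdb	gene	6144589	6150509	.	+	.	ID=Os10g0188900;description=Conserved hypothetical protein;nSNP=43;ZHp=-1.65
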