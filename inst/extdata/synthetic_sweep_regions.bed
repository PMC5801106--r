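# coordinates: 0-based half-open (BED)
# SYNTHETIC stand-in: the published screen does not print its merged sweep
# regions, so these are the 100-kb-aligned hulls of the published candidate
# gene clusters; the fifth column is the minimum published ZHp per cluster.
chr4	5100000	5300000	sweep_region_1	-1.59
chr5	15800000	16000000	sweep_region_2	-1.58
chr10	4200000	4300000	sweep_region_3	-1.52
chr10	5100000	5300000	sweep_region_4	-1.59
chr10	6000000	6200000	sweep_region_5	-1.65
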