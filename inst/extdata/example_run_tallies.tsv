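sample_id	mapped_reads	mapped_bases	snv_count	coding_snv_count
MID1	35243	9900000	247	66
MID2	30264	8600000	215	50
MID3	2739	800000	27	8
MID4	22952	6400000	217	55
MID5	30869	8500000	230	46
MID6	18608	5200000	221	63
MID7	20239	5600000	185	48
MID8	38539	10700000	252	53
MID9	7815	2200000	129	34
MID10	40046	11400000	259	65
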