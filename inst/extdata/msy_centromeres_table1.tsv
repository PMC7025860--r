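# Published coordinates (1-based) of the M. sympodialis core and
# full-length (Mtw1-bound) centromeres; printed lengths are authoritative.
# Genome average GC content: 58.5%.
chrom	core_start	core_end	core_len	core_gc_percent	full_start	full_end	full_len
MsyChr1	786541	787061	520	16.4	784833	788599	3767
MsyChr2	355760	355841	81	20	354218	357486	3269
MsyChr3	237534	238686	1152	15.6	235615	239940	4326
MsyChr4	418202	418728	526	15.2	415985	420656	4672
MsyChr5	125056	125220	164	18	123219	127284	4066
MsyChr6	101950	102502	552	14.4	100342	105251	4910
MsyChr7	431542	431987	445	13.2	430028	433194	3167
MsyChr8	24694	25564	870	18.4	22334	27476	5143
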