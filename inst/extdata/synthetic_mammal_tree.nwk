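(((Homo_sapiens:7,Pan_troglodytes:7):82,((Cavia_porcellus:41,Heterocephalus_glaber:41):30,Mus_musculus:71):18):7,((Balaena_mysticetus:34,Tursiops_truncatus:34):22,Bos_taurus:56):40);
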