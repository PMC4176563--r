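@r01_kept_22nt
ACGTACGTACGTACGTACGTACTGGAATTCTCGGGT
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@r02_kept_18nt_flank18
GCGCGCATATGCGCATATTGGAATTCTCGGGTGCCA
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@r03_kept_20nt_readthrough
ACCGTTACCGTTACCGTTACTGGAATTCTCGGGTGCCAAGG
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@r04_kept_26nt_flank6
ACGGATCCGATTACGGATCCGATTACTGGAAT
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@r05_no_adapter
GTACCTAGCATGGTACCTAGCATGGTACCTAGCATG
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@r06_flank_only_5nt
ACGTACGTACGTACGTACGTATGGAA
+
IIIIIIIIIIIIIIIIIIIIIIIIII
@r07_adapter5_at_start
GTTCAGAGTTCTACAGTCCGACGATCACGTTGGAATTCTCGGGT
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@r08_adapter5_offset3
ACGGTTCAGAGTTCTACAGTCCGACGATCACGTAC
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@r09_ambiguous_N
ACGNACGTACGTACGTACGTACTGGAATTCTCGGGT
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@r10_polyA_insert
AAAAAAAAAAAAAAAAAAAAAATGGAATTCTCGGGT
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@r11_polyA_terminal_run
ACGTACGTACGTAAAAAAAAAATGGAATTCTCGGGT
+
IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
@r12_too_short_10nt
ACGTACGTACTGGAATTCTCGGGTGCCA
+
IIIIIIIIIIIIIIIIIIIIIIIIIIII
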