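#!/usr/bin/env Rscript
# Step 1: generate every input the downstream analyses consume.
#
# Three synthetic datasets stand in for the downloads a real study would use:
#   (a) a deep paired alignment sampled from a two-domain Potts model with a
#       planted diagonal interface (10 coupled pairs, strength 1.5), the
#       stand-in for a paralog-matched subunit-pair MSA;
#   (b) a shallow, conserved, paralog-rich family pair (50 species, 2
#       paralogs each) exercising the progressive paralog matcher;
#   (c) a toy two-chain bead complex realizing the same planted interface at
#       8 A, plus a 10-true / 10-decoy crosslink table against it.

suppressPackageStartupMessages(library(coevodock))
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)
seed <- 1L

# planted interface: diagonal patch, domain-A residues 11..20 against
# domain-B residues 1..10
planted <- data.frame(i = 11:20, j = 1:10, strength = 1.5)
write.table(planted, "results/inputs/planted_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## (a) deep coupled alignment, 5000 species, occasional long gap runs
pm <- planted_model(30, 30, 21, planted, seed = seed)
deep <- sample_potts_msa(pm, 5000, gap_run_fraction = 0.1, gap_run_length = 0.3)
write_msa(deep$msa_a, "results/inputs/deep_A.fasta")
write_msa(deep$msa_b, "results/inputs/deep_B.fasta")
cat(sprintf("deep MSA: %d rows per family, L = 30 + 30, 10 planted pairs\n",
            nrow(deep$msa_a$mat)))

## (b) conserved paralog benchmark family
pmp <- planted_model(30, 30, 21, field_bias = 4, seed = seed + 1L)
par <- sample_potts_msa(pmp, 50, n_paralogs = 2, seed = seed + 1L)
write_msa(par$msa_a, "results/inputs/paralog_A.fasta")
write_msa(par$msa_b, "results/inputs/paralog_B.fasta")
write.table(par$pairing, "results/inputs/paralog_truth.tsv", sep = "\t",
            quote = TRUE, row.names = FALSE)
cat(sprintf("paralog family: %d species x 2 paralogs, truth table saved\n", 50))

## (c) toy complex with the planted interface at 8 A + crosslink table
iface <- data.frame(chain_a = "A", res_a = planted$i,
                    chain_b = "B", res_b = planted$j)
cx <- make_toy_complex(c(30, 30), iface, target_distance = 8)
write_structure(cx$model, "results/inputs/toy_complex.pdb")
xl <- make_synthetic_crosslinks(cx, 10, 10, max_true_distance = 35,
                                seed = seed + 2L)
write_crosslinks(xl, "results/inputs/crosslinks.tsv")
cat(sprintf("toy complex: chains A/B (30 + 30 beads), %d interface pairs at 8 A\n",
            nrow(iface)))
cat(sprintf("crosslinks: %d true (<= 35 A) + %d decoys (> 35 A)\n", 10, 10))
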