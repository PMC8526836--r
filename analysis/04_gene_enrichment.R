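#!/usr/bin/env Rscript
# Stage 4: imaging-transcriptomics decoding and enrichment. A synthetic
# donor-wise expression atlas is generated with a planted subset of genes
# whose spatial expression tracks a reference imaging map; genes are decoded
# by donor-specific regression slopes + one-sample t (positive t, FDR
# q < 0.05), and the decoded list is tested for overlap with a pruned
# "interactome" set via odds ratio and hypergeometric p.

library(dmfconn)

dir.create("results", showWarnings = FALSE)

at <- make_expression_atlas(n_donors = 6, n_genes = 1000, n_locations = 200,
                            n_coupled = 50, beta = 1, noise_sd = 0.2,
                            seed = 4)
dec <- decode_genes(donor_slopes(at, at$map), q_threshold = 0.05)
kept <- attr(dec, "genes")
planted <- at$genes[at$ground_truth$planted_gene_indices]
message(sprintf("decoded %d genes (%d/%d planted recovered)", length(kept),
                length(intersect(kept, planted)), length(planted)))
write_gene_list(kept, "results/decoded_genes.txt")

# interactome pruning: a broad interactor list cut down to its dysregulated
# members (here: half the planted genes plus background)
interactors <- list(members = c(planted[1:30], at$genes[900:980]),
                    universe = at$genes)
dysregulated <- c(planted[11:50], at$genes[940:1000])
target <- prune_interactome(interactors, dysregulated)
message(sprintf("interactome pruned from %d to %d genes",
                length(interactors$members), length(target$members)))

res <- enrich(dec, target)
print(res)
jsonlite::write_json(list(overlap = res$overlap_k, size_decoded = res$size_A,
                          size_target = res$size_B, universe = res$N,
                          odds_ratio = res$odds_ratio,
                          p_hypergeometric = res$p_hypergeometric),
                     "results/enrichment.json", auto_unbox = TRUE, digits = NA)

# the textbook worked example on a 10-gene universe
gl <- make_gene_lists(10, 5, 4, 3, seed = 2)
ex <- enrich(gl$list_a, list(members = gl$list_b, universe = gl$universe))
message(sprintf("worked example (k=3, A=5, B=4, N=10): OR = %.1f, p = %.6f",
                ex$odds_ratio, ex$p_hypergeometric))
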