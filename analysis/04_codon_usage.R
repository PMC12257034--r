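#!/usr/bin/env Rscript
# Codon usage of the annotated CDS set: counts, RSCU, third-base bias and
# start/stop codon screen. Writes results/codon_usage/.

suppressMessages(library(mitokit))

sim <- "results/simdata"
out <- "results/codon_usage"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cds <- vapply(read_fasta(file.path(sim, "cds.fasta")), function(r) r$seq, "")
counts <- count_codons(cds)
rscu <- compute_rscu(counts)
bias <- rscu_bias_summary(rscu)

rscu_out <- rscu
rscu_out$rscu <- round(rscu_out$rscu, 2)
write.table(rscu_out, file.path(out, "rscu.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(check_start_stop(cds), file.path(out, "start_stop.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(bias, file.path(out, "bias.json"), auto_unbox = TRUE,
                     digits = NA)

au <- bias$third_base$pct[bias$third_base$ending == "A/U"]
message(counts$total, " codons over ", counts$n_cds, " unique CDS; ",
        bias$n_over_1, " codons with RSCU > 1, of which ", au,
        "% end in A or U; most frequent amino acid: ",
        bias$aa_usage$aa[1], " (", bias$aa_usage$count[1], " codons, ",
        bias$aa_usage$pct[1], "%)")
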