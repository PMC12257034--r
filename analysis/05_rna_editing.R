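#!/usr/bin/env Rscript
# C-to-U editing: call sites from the simulated RNA reads, classify the
# hydropathy effects, check recall against the planted edits, and summarise
# the bundled published transition table the same way.
# Writes results/editing/.

suppressMessages(library(mitokit))

sim <- "results/simdata"
out <- "results/editing"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cds <- vapply(read_fasta(file.path(sim, "cds.fasta")), function(r) r$seq, "")
rna <- read_fastq(file.path(sim, "rna.fastq"))
truth <- read_truth(file.path(sim, "truth"))

sites <- call_editing_sites(rna, cds)
write.table(sites, file.path(out, "sites.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
es <- editing_summary(sites)
write.table(es$by_category, file.path(out, "categories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(es$by_gene, file.path(out, "per_gene.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tk <- paste(truth$edits$gene, truth$edits$cds_pos)
ck <- paste(sites$gene, sites$cds_pos)
message(nrow(sites), " sites called; recall ",
        sprintf("%.3f", mean(tk %in% ck)), ", false positives ",
        sum(!(ck %in% tk)))

# the same census over the published transition table
ref <- reference_table("editing_transitions")
ers <- editing_summary(ref)
write.table(ers$by_category, file.path(out, "reference_categories.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("published transition table: ", ers$total, " sites; ",
        "hydrophilic->hydrophobic ",
        ers$by_category$pct[ers$by_category$category ==
                              "hydrophilic-hydrophobic"], "%")
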