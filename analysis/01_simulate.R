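#!/usr/bin/env Rscript
# Build the synthetic study bundle every later step consumes: a circular
# mitogenome with a planted repeat landscape and annotated genes, long DNA
# reads with 30% labelled contaminants, RNA reads carrying C-to-U edits,
# a plastid genome with transfer fragments, and per-gene homolog sets —
# all with machine-readable ground truth under results/simdata/.

suppressMessages(library(mitokit))

out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

edit_plan <- data.frame(gene = rep(sprintf("gene%02d", 1:4), each = 4),
                        codon_index = rep(c(60, 75, 90, 110), 4),
                        codon_pos = rep(c(2, 1, 2, 1), 4),
                        fraction = rep(c(0.9, 0.5, 1.0, 0.7), 4))
cfg <- generator_config(seed = 2024, genome_length = 22000, n_genes = 4,
                        gene_length_range = c(600, 900),
                        edit_plan = edit_plan)
g <- generate_genome(cfg)
message("genome: ", g$genome$id, ", ", nchar(g$genome$seq), " bp, ",
        nrow(g$truth$ssrs), " SSRs / ", nrow(g$truth$tandems),
        " tandem / ", nrow(g$truth$dispersed), " dispersed planted, ",
        length(g$cds), " genes, ", nrow(g$truth$edits), " edit sites")

write_fasta(g$genome, file.path(out, "genome.fasta"))
write_gff3(g$annotation, g$genome$id, file.path(out, "genes.gff3"))
write_fasta(setNames(as.character(g$cds), names(g$cds)),
            file.path(out, "cds.fasta"))

prof <- default_read_profile()
prof$depth <- 30
prof$contaminant_fraction <- 0.3
rd <- generate_reads(g$genome, g$truth, cds = g$cds, profile = prof,
                     seed = 2025)
message("reads: ", length(rd$dna_reads), " DNA (",
        sum(rd$dna_truth$origin == "mito"), " mitochondrial), ",
        length(rd$rna_reads), " RNA")
write_fastq(rd$dna_reads, file.path(out, "dna.fastq"))
write_fastq(rd$rna_reads, file.path(out, "rna.fastq"))
write.table(rd$dna_truth, file.path(out, "read_origins.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

plan <- rbind(data.frame(length = c(500, 300, 150, 100),
                         identity = c(1, 0.95, 0.9, 0.85)),
              data.frame(length = 300, identity = 0.6))
pl <- generate_plastid_with_transfers(g$genome, plan, seed = 2026)
write_fasta(pl$plastid, file.path(out, "plastid.fasta"))
write.table(pl$truth, file.path(out, "transfer_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

hd <- file.path(out, "homologs")
dir.create(hd, showWarnings = FALSE)
for (gid in names(g$cds)) {
  hs <- generate_homolog_set(
    g$cds[[gid]],
    data.frame(species = c("spA", "spB"), ks = c(0.2, 0.05),
               ka = c(0.02, 0.005)),
    seed = 2027 + match(gid, names(g$cds)))
  write_fasta(setNames(as.character(hs$sequences), names(hs$sequences)),
              file.path(hd, paste0(gid, ".fasta")))
}

write_truth(g$truth, file.path(out, "truth"))
message("bundle written to ", out)
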