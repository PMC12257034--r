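#!/usr/bin/env Rscript
# One-shot orchestration: run every stage over the simulated bundle through
# the pipeline driver and write the consolidated report to
# results/pipeline/report.json.

suppressMessages(library(mitokit))

sim <- "results/simdata"
cfg <- pipeline_config(
  genome_fasta = file.path(sim, "genome.fasta"),
  annotation_gff3 = file.path(sim, "genes.gff3"),
  cds_fasta = file.path(sim, "cds.fasta"),
  dna_reads_fastq = file.path(sim, "dna.fastq"),
  core_genes_fasta = file.path(sim, "cds.fasta"),
  rna_reads_fastq = file.path(sim, "rna.fastq"),
  plastid_fasta = file.path(sim, "plastid.fasta"),
  homolog_dir = file.path(sim, "homologs"),
  out_dir = "results/pipeline", seed = 2024)
report <- run_pipeline(cfg)
message("stages: ",
        paste(names(report$stages), unlist(report$stages),
              sep = "=", collapse = ", "))
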