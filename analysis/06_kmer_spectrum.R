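#!/usr/bin/env Rscript
# Stage 6: k-mer abundance spectrum of the short reads and shape
# classification (monomodal / bimodal / no-peak), the genome-character
# diagnostic that flags a clonal mutation-dense genome.

suppressPackageStartupMessages(library(clonemut))

outdir <- "results/run"
reads <- c(read_fastq(file.path(outdir, "reads_R1.fastq")),
           read_fastq(file.path(outdir, "reads_R2.fastq")))

spec <- kmer_spectrum(unname(reads), 21)
shape <- classify_spectrum(spec)
clonemut:::write_tsv(spec$histogram, file.path(outdir, "kmer_histogram.tsv"))
jsonlite::write_json(list(k = spec$k, classification = shape$classification,
                          peaks = shape$peaks,
                          noise_boundary = shape$noise_boundary),
                     file.path(outdir, "kmer_shape.json"),
                     auto_unbox = TRUE, null = "null")

cat(sprintf("k=21 spectrum over %d k-mers (%d distinct): %s\n",
            spec$total_kmers, spec$distinct_kmers, shape$classification))
if (length(shape$peaks))
  cat("peak abundance(s):", paste(shape$peaks, collapse = ", "), "\n")
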