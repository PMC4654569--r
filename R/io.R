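#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads to FASTQ (Sanger phred+33, constant quality)
#' @param seqs named character vector of read sequences.
#' @param path output file.
#' @param qual constant per-base quality character (default "I", Q40).
#' @export
write_fastq <- function(seqs, path, qual = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(strrep(qual, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Serialize a contig graph to plain-text files
#'
#' Writes `contigs.fasta`, `isotigs.fasta`, `edges.tsv`
#' (gene_id/from/to), `isotig_paths.tsv` (gene_id/isotig_id/path with
#' comma-joined contig ids) and `members.tsv` (gene_id/contig_id) under
#' `dir`.
#'
#' @param graph a [contig_graph()].
#' @param dir output directory (created if missing).
#' @export
write_contig_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(graph$contigs, file.path(dir, "contigs.fasta"))
  write_fasta(setNames(graph$isotigs$sequence, graph$isotigs$isotig_id),
              file.path(dir, "isotigs.fasta"))
  write_tsv(graph$edges, file.path(dir, "edges.tsv"))
  paths <- data.frame(gene_id = graph$isotigs$gene_id,
                      isotig_id = graph$isotigs$isotig_id,
                      path = vapply(graph$isotigs$path, paste,
                                    character(1), collapse = ","),
                      stringsAsFactors = FALSE)
  write_tsv(paths, file.path(dir, "isotig_paths.tsv"))
  write_tsv(data.frame(gene_id = unname(graph$contig_gene),
                       contig_id = names(graph$contig_gene),
                       stringsAsFactors = FALSE),
            file.path(dir, "members.tsv"))
  invisible(dir)
}

#' Read a contig graph written by [write_contig_graph()]
#' @param dir directory holding the serialized graph.
#' @return a [contig_graph()].
#' @export
read_contig_graph <- function(dir) {
  contigs <- read_fasta(file.path(dir, "contigs.fasta"))
  iso_seq <- read_fasta(file.path(dir, "isotigs.fasta"))
  edges <- read_tsv(file.path(dir, "edges.tsv"))
  paths <- read_tsv(file.path(dir, "isotig_paths.tsv"))
  members <- read_tsv(file.path(dir, "members.tsv"))
  isotigs <- data.frame(gene_id = paths$gene_id,
                        isotig_id = paths$isotig_id,
                        sequence = unname(iso_seq[paths$isotig_id]),
                        stringsAsFactors = FALSE)
  isotigs$path <- strsplit(paths$path, ",", fixed = TRUE)
  contig_graph(contigs = contigs,
               contig_gene = setNames(members$gene_id, members$contig_id),
               edges = edges, isotigs = isotigs)
}

#' Write Reference Gene Models to FASTA + offsets BED
#'
#' One FASTA record per gene (the virtual intron-less sequence) and a BED
#' table of 0-based half-open contig intervals (gene_id, start, end,
#' contig_id), plus the representative-isotig table.
#'
#' @param models named list from [build_gene_models()].
#' @param fasta_path,bed_path,rep_path output files (NULL to skip one).
#' @export
write_gene_models <- function(models, fasta_path, bed_path = NULL,
                              rep_path = NULL) {
  seqs <- vapply(models, `[[`, character(1), "virtual_sequence")
  write_fasta(setNames(seqs, names(models)), fasta_path)
  if (!is.null(bed_path)) {
    bed <- do.call(rbind, lapply(models, function(m)
      cbind(gene_id = m$gene_id, m$offsets)))
    write_tsv(bed[, c("gene_id", "start", "end", "contig_id")], bed_path)
  }
  if (!is.null(rep_path)) {
    write_tsv(data.frame(
      gene_id = names(models),
      representative_isotig_id = vapply(models, `[[`, character(1),
                                        "representative_isotig_id"),
      stringsAsFactors = FALSE), rep_path)
  }
  invisible(fasta_path)
}

#' Write alignments as SAM
#'
#' Emits proper `@SQ` headers for the reference set and one record per
#' alignment with soft-clipped unaligned read ends, `AS` (score) and `NM`
#' (edit distance) tags. Sequences are stored in reference orientation
#' (reverse-complemented reads carry flag 16). Ambiguous reads get MAPQ 0.
#'
#' @param alignments alignment table from [map_reads()].
#' @param reads named character vector of (possibly trimmed) read
#'   sequences used at mapping time.
#' @param references named character vector of reference sequences.
#' @param path output SAM file.
#' @export
write_sam <- function(alignments, reads, references, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (ref in names(references))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ref, nchar(references[[ref]])),
               con)
  writeLines("@PG\tID:clonemut\tPN:clonemut", con)
  if (nrow(alignments)) {
    seq_used <- unname(reads[alignments$read_id])
    neg <- alignments$strand == "-"
    seq_used[neg] <- revcomp_chr(seq_used[neg])
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tAS:i:%d\tNM:i:%d",
                     alignments$read_id,
                     ifelse(neg, 16L, 0L),
                     alignments$gene_id,
                     alignments$start + 1L,
                     ifelse(alignments$ambiguous, 0L, 60L),
                     alignments$cigar,
                     seq_used,
                     as.integer(round(alignments$score)),
                     alignments$nm)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write variant calls as VCF v4.2
#'
#' Coordinates are 1-based against the gene-model references. Deletions
#' are left-anchored on the preceding base, insertions on the base they
#' follow. INFO carries DP (depth), AC (per-alt counts) and AF (per-alt
#' fractions); the FILTER column holds the clonal-filter status.
#'
#' @param calls calls from [call_variants()] / [filter_clonal()].
#' @param references named character vector of reference sequences.
#' @param path output VCF file.
#' @export
write_variant_vcf <- function(calls, references, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=clonemut",
    sprintf("##contig=<ID=%s,length=%d>", names(references),
            nchar(references)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site read depth\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alt allele counts\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alt allele fractions\">",
    "##FILTER=<ID=ancestral_or_platform,Description=\"Allelic fraction in the excluded ancestral (near 0.5) or platform-bias (near 1.0) range\">",
    "##FILTER=<ID=low_depth,Description=\"Depth below the minimum\">",
    "##FILTER=<ID=low_fraction,Description=\"All alt fractions below the retained windows\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      v <- calls[i, ]
      refseq <- references[[v$gene_id]]
      if (v$class == "SNP") {
        pos1 <- v$pos + 1L; ref <- v$ref; alt <- v$alt
      } else if (v$class == "deletion") {
        pos1 <- v$pos                       # anchor on the preceding base
        if (pos1 < 1L) next
        anchor <- substr(refseq, pos1, pos1)
        ref <- paste0(anchor, v$ref); alt <- anchor
      } else {                              # insertion after v$pos
        pos1 <- v$pos + 1L
        anchor <- substr(refseq, pos1, pos1)
        ref <- anchor
        alt <- paste0(anchor, sub("^\\+", "", v$alt))
      }
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;AC=%s;AF=%s",
                         v$gene_id, pos1, ref, alt,
                         if (v$filter == ".") "." else v$filter,
                         v$depth, v$alt_count, v$alt_fraction), con)
    }
  }
  invisible(path)
}
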