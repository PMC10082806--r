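# Writes a per-read call table in the on-disk dialect and returns its path.
writeCallFixture <- function(rows, path = tempfile(fileext = ".tsv")) {
    header <- paste("chromosome", "strand", "start", "end", "read_name",
                    "log_lik_ratio", "log_lik_methylated",
                    "log_lik_unmethylated", "num_calling_strands",
                    "num_motifs", "sequence", sep = "\t")
    writeLines(c(header, rows), path)
    path
}

callRow <- function(chrom = "chr1", strand = "+", start = 100, end = 102,
                    read = "r1", llr = 3.0, nMotifs = 1) {
    paste(chrom, strand, start, end, read, llr, 0, 0, 1, nMotifs, "ACGCGT",
          sep = "\t")
}
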