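# compact builders for hand-sized fixtures used across the suite

# snp_table from vectors; gt is a character matrix (or vector for 1 sample),
# dp defaults to a constant comfortably inside all depth rules
make_table <- function(chrom, pos, gt, dp = NULL,
                       qd = 30, fs = 1, mq = 60, sor = 1, mqranksum = 0,
                       ref = "A", alt = "T",
                       samples = NULL) {
  gt <- as.matrix(gt)
  n <- length(pos)
  if (is.null(dp)) dp <- matrix(50L, n, ncol(gt))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(gt)))
  sites <- data.frame(
    chrom = rep_len(chrom, n), pos = pos,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    qd = rep_len(qd, n), fs = rep_len(fs, n), mq = rep_len(mq, n),
    sor = rep_len(sor, n), mqranksum = rep_len(mqranksum, n),
    stringsAsFactors = FALSE
  )
  snp_table(sites, gt, dp, samples)
}

# single-row table with chosen INFO metrics, for hard-filter boundary tests
one_site <- function(qd = 30, fs = 1, mq = 60, sor = 1, mqranksum = 0) {
  make_table("chr1", 100L, matrix("0/1", 1, 2),
             qd = qd, fs = fs, mq = mq, sor = sor, mqranksum = mqranksum)
}

# write a small VCF fixture file; body rows are character vectors of fields
write_test_vcf <- function(path, samples, rows,
                           format = "GT:DP") {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="qd">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="fs">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="mq">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="sor">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="mqrs">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="dp">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, vapply(rows, paste, character(1L), collapse = "\t")),
             path)
  path
}

# profile whose first n_match markers carry genotype "AA" and the rest differ
# between the pair; used for GS worked examples
profiles_with_overlap <- function(n_markers, n_match,
                                  strains = c("a", "b")) {
  ids <- sprintf("m%04d", seq_len(n_markers))
  gcall <- function(hap) {
    structure(list(haplotypes = hap, support = structure(50L, names = hap[1]),
                   total_reads = 50L, missing = FALSE),
              class = "mnp_genotype")
  }
  calls_a <- lapply(seq_len(n_markers), function(i) gcall("AA"))
  calls_b <- lapply(seq_len(n_markers), function(i) {
    if (i <= n_match) gcall("AA") else gcall("TT")
  })
  names(calls_a) <- names(calls_b) <- ids
  list(a = mnp_profile(strains[1], calls_a),
       b = mnp_profile(strains[2], calls_b))
}

# minimal marker data.frame with k markers (for genotyping tests)
toy_markers <- function(ids) {
  df <- data.frame(
    marker_id = ids, chrom = rep_len("chr1", length(ids)),
    start = seq(1L, by = 60000L, length.out = length(ids)),
    n_snps = rep_len(2L, length(ids)), pic = rep_len(0.8, length(ids)),
    stringsAsFactors = FALSE
  )
  df$end <- df$start + 99L
  df$snp_positions <- lapply(df$start, function(s) c(s, s + 10L))
  df[, c("marker_id", "chrom", "start", "end", "n_snps", "snp_positions", "pic")]
}
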