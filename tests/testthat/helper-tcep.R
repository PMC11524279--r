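# Shared fixtures and independent oracles, all built in code.

noiseless <- function(ct_baseline = 20) {
  readout_params(ct_baseline = ct_baseline, ct_noise_sd = 0)
}

# Independent brute-force site scanner: explicit double loop over both
# strands, no regex, its own complement table. Mirrors the documented
# policy (spacer length 20, PAM NGG, N never matches, sites running off
# the sequence skipped).
naive_scan <- function(seq, spacer_len = 20) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  acgt <- c("A", "C", "G", "T")
  rows <- list()
  for (p0 in 0:(L - 3)) {                      # forward PAM [p0, p0+3)
    if (p0 - spacer_len < 0) next
    if (!(ch[p0 + 1] %in% acgt)) next
    if (ch[p0 + 2] != "G" || ch[p0 + 3] != "G") next
    spacer <- ch[(p0 - spacer_len + 1):p0]
    if (!all(spacer %in% acgt)) next
    rows[[length(rows) + 1L]] <- data.frame(
      strand = "+", spacer = paste(spacer, collapse = ""),
      pam = paste(ch[(p0 + 1):(p0 + 3)], collapse = ""),
      pam_start = p0, cut_pos = p0 - 3,
      spacer_start = p0 - spacer_len, spacer_end = p0,
      stringsAsFactors = FALSE)
  }
  for (q0 in 0:(L - 3)) {                      # reverse PAM complement CCN
    if (q0 + 3 + spacer_len > L) next
    if (ch[q0 + 1] != "C" || ch[q0 + 2] != "C") next
    if (!(ch[q0 + 3] %in% acgt)) next
    spacer_fwd <- ch[(q0 + 4):(q0 + 3 + spacer_len)]
    if (!all(spacer_fwd %in% acgt)) next
    rows[[length(rows) + 1L]] <- data.frame(
      strand = "-",
      spacer = paste(rev(comp[spacer_fwd]), collapse = ""),
      pam = paste(rev(comp[ch[(q0 + 1):(q0 + 3)]]), collapse = ""),
      pam_start = q0, cut_pos = q0 + 6,
      spacer_start = q0 + 3, spacer_end = q0 + 3 + spacer_len,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(strand = character(0), spacer = character(0),
                      pam = character(0), pam_start = integer(0),
                      cut_pos = integer(0), spacer_start = integer(0),
                      spacer_end = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pam_start, match(out$strand, c("+", "-"))), ]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# Hand-built in vivo Ct table for one target: explicit control over each
# well, independent of the simulator.
manual_records <- function(target_id = "t1", ct_t, ct_t_inter = 20,
                           ct_cas = 20, ct_rna_inter = 20,
                           ct_c = 20, ct_c_inter = 20,
                           replicate = 1, condition = "control") {
  rbind(
    data.frame(sample_id = paste0("test_", replicate), target_id = target_id,
               assay_id = "amp", role = "target_region", template = "genomic_dna",
               group = "test", condition = condition, replicate = replicate,
               ct = ct_t, stringsAsFactors = FALSE),
    data.frame(sample_id = paste0("test_", replicate), target_id = target_id,
               assay_id = "gref", role = "genomic_reference", template = "genomic_dna",
               group = "test", condition = condition, replicate = replicate,
               ct = ct_t_inter, stringsAsFactors = FALSE),
    data.frame(sample_id = paste0("test_", replicate), target_id = target_id,
               assay_id = "cas9", role = "cas9_transcript", template = "cdna",
               group = "test", condition = condition, replicate = replicate,
               ct = ct_cas, stringsAsFactors = FALSE),
    data.frame(sample_id = paste0("test_", replicate), target_id = target_id,
               assay_id = "tref", role = "transcript_reference", template = "cdna",
               group = "test", condition = condition, replicate = replicate,
               ct = ct_rna_inter, stringsAsFactors = FALSE),
    data.frame(sample_id = paste0("ctrl_", replicate), target_id = target_id,
               assay_id = "amp", role = "target_region", template = "genomic_dna",
               group = "control", condition = condition, replicate = replicate,
               ct = ct_c, stringsAsFactors = FALSE),
    data.frame(sample_id = paste0("ctrl_", replicate), target_id = target_id,
               assay_id = "gref", role = "genomic_reference", template = "genomic_dna",
               group = "control", condition = condition, replicate = replicate,
               ct = ct_c_inter, stringsAsFactors = FALSE))
}

invitro_records <- function(target_id = "t1", ct_a, ct_inter = 20, replicate = 1) {
  rbind(
    data.frame(sample_id = "digest", target_id = target_id, assay_id = "amp",
               role = "invitro_target", template = "purified_dna",
               group = "test", condition = "invitro", replicate = replicate,
               ct = ct_a, stringsAsFactors = FALSE),
    data.frame(sample_id = "digest", target_id = target_id, assay_id = "ref",
               role = "invitro_reference", template = "purified_dna",
               group = "test", condition = "invitro", replicate = replicate,
               ct = ct_inter, stringsAsFactors = FALSE))
}
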