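# End-to-end quantification of a transient-editing qPCR experiment.

#' Quantify Cas9 cutting efficiency from a Ct table
#'
#' The central estimator of the package. Takes the long-format well table
#' of an in vivo transient-editing experiment (see [validate_ct_records()])
#' and returns per-target cutting efficiencies with replicate spread,
#' fold-normalisation to the weakest target, and Student's t-tests between
#' treatment conditions.
#'
#' For every biological replicate of every target the chain is:
#' delta-delta-Ct of the cut-site amplicon against the internal genomic
#' reference and the untreated control plants ([broken_dna_abundance()]),
#' Cas9 transcript abundance from the cDNA assays ([cas9_abundance()]),
#' and their ratio ([relative_cutting_efficiency()]).
#'
#' Aggregation follows qPCR practice: the reported point estimates of
#' `ddct`, the intact/broken fractions and `cas9_abundance` come from the
#' replicate-mean Ct values (delta-delta-Ct is linear in Ct, so this equals
#' the mean of per-replicate delta-delta-Ct), while `relative_efficiency`,
#' its `sd` and the t-tests use the per-replicate efficiencies, which keep
#' the replicate-to-replicate spread.
#'
#' Replicate pairing against the untreated controls is either
#' `"mean_control"` (default: each test replicate against the control-group
#' mean Ct — controls are independent wild-type plants with no natural
#' pairing) or `"per_replicate"` (index-matched control replicate).
#'
#' A test replicate missing any required role (or with an undetermined Ct
#' in one) is dropped with a warning naming the role; a target with no
#' usable replicate is excluded from normalisation and flagged. Mean
#' efficiencies at or below zero (possible under noise, when the
#' delta-delta-Ct is negative) are clamped to `clamp_floor` and flagged
#' before fold-normalisation, which requires positive values; if no target
#' has a positive efficiency the normalised column is `NA` and a warning is
#' raised, since fold changes over noise are meaningless.
#'
#' @param records Data frame of Ct records (see [read_ct_table()]).
#' @param mode `"canonical"` (broken fraction, default) or `"literal"`
#'   (intact fraction \eqn{2^{-\Delta\Delta Ct}}) as the abundance entering
#'   the efficiency ratio; see [broken_dna_abundance()].
#' @param pairing `"mean_control"` or `"per_replicate"`.
#' @param alpha Significance level for the condition t-tests (default 0.05).
#' @param clamp_floor Positive floor applied to non-positive mean
#'   efficiencies before fold-normalisation.
#' @param compare Length-2 character vector of condition labels to t-test
#'   against each other per target; `NULL` (default) auto-selects when the
#'   table contains exactly two conditions.
#' @return An object of class `"tcep_quant"`: a list with `results` (one
#'   row per target and condition), `replicates` (per-replicate chain
#'   values), `reference` (the target(s) set to 1), `flags`, and the
#'   settings used. Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' rec <- simulate_tcep_experiment(c(ts1 = 0.5, ts2 = 0.75),
#'                                 readout = readout_params(ct_noise_sd = 0))
#' fit <- tcep_quantify(rec)
#' coef(fit) # ts2 is 1.5-fold ts1
#' @export
tcep_quantify <- function(records,
                          mode = c("canonical", "literal"),
                          pairing = c("mean_control", "per_replicate"),
                          alpha = 0.05, clamp_floor = 1e-6, compare = NULL) {
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  stopifnot(is.numeric(clamp_floor), clamp_floor > 0)
  records <- validate_ct_records(records)
  vivo <- records[records$role %in% c("target_region", "genomic_reference",
                                      "cas9_transcript", "transcript_reference"), ,
                  drop = FALSE]
  if (nrow(vivo) == 0) stop("no in vivo Ct records found", call. = FALSE)

  tests <- vivo[vivo$group == "test", , drop = FALSE]
  ctrls <- vivo[vivo$group == "control", , drop = FALSE]
  if (nrow(tests) == 0) stop("no test-group records found", call. = FALSE)
  if (nrow(ctrls) == 0) stop("no control-group records found", call. = FALSE)

  reps <- list()
  flags <- character(0)
  for (tid in unique(tests$target_id)) {
    tt <- tests[tests$target_id == tid, , drop = FALSE]
    for (cond in unique(tt$condition)) {
      tc <- tt[tt$condition == cond, , drop = FALSE]
      ctl <- ctrls[ctrls$target_id == tid & ctrls$condition == cond, , drop = FALSE]
      if (nrow(ctl) == 0) {
        # untreated wild-type controls are shared across treatment arms
        ctl <- ctrls[ctrls$target_id == tid, , drop = FALSE]
      }
      if (nrow(ctl) == 0) {
        flags <- c(flags, sprintf("target %s: no control records; skipped", tid))
        warning(sprintf("target %s: no control records; skipped", tid), call. = FALSE)
        next
      }
      for (r in sort(unique(tc$replicate))) {
        row <- .replicate_chain(tc, ctl, tid, cond, r, pairing, mode)
        if (is.character(row)) {
          flags <- c(flags, row)
          warning(row, call. = FALSE)
        } else {
          reps[[length(reps) + 1L]] <- row
        }
      }
    }
  }
  if (length(reps) == 0) {
    stop("no usable replicates: every replicate was missing a required role",
         call. = FALSE)
  }
  repdf <- do.call(rbind, reps)

  key <- interaction(repdf$target_id, repdf$condition, drop = TRUE, lex.order = TRUE)
  res <- do.call(rbind, lapply(split(repdf, key), function(d) {
    ddct <- mean(d$ddct)
    intact <- 2^(-ddct)
    data.frame(target_id = d$target_id[1], condition = d$condition[1],
               mode = mode, ddct = ddct,
               intact_fraction = intact, broken_fraction = 1 - intact,
               cas9_abundance = 2^(-mean(d$dct_cas)),
               relative_efficiency = mean(d$efficiency),
               sd = stats::sd(d$efficiency), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res$sd[is.na(res$sd)] <- 0  # single replicate: no spread to report

  # fold-normalisation across all target x condition cells
  eff <- res$relative_efficiency
  res$clamped <- eff <= 0
  if (any(res$clamped)) {
    flags <- c(flags, sprintf("%d target(s) with non-positive mean efficiency clamped to %g for normalisation",
                              sum(res$clamped), clamp_floor))
  }
  if (all(eff <= 0)) {
    warning("no target shows a positive cutting efficiency; fold-normalisation is not meaningful (normalized_efficiency set to NA)",
            call. = FALSE)
    res$normalized_efficiency <- NA_real_
    reference <- NA_character_
  } else {
    clamped_eff <- pmax(eff, clamp_floor)
    names(clamped_eff) <- paste(res$target_id, res$condition, sep = "/")
    norm <- normalize_to_lowest(clamped_eff)
    res$normalized_efficiency <- as.numeric(norm)
    reference <- res$target_id[which.min(clamped_eff)]
    if (any(res$clamped)) {
      warning("non-positive mean efficiency clamped before fold-normalisation; interpret folds with care",
              call. = FALSE)
    }
  }

  # between-condition t-test on per-replicate efficiencies
  conds <- unique(repdf$condition)
  if (is.null(compare) && length(conds) == 2) compare <- conds
  res$p_value <- NA_real_
  res$t_statistic <- NA_real_
  if (!is.null(compare)) {
    if (length(compare) != 2) stop("compare must name exactly two conditions", call. = FALSE)
    if (!all(compare %in% conds)) {
      stop("compare names a condition absent from the data: ",
           paste(setdiff(compare, conds), collapse = ", "), call. = FALSE)
    }
    for (tid in unique(res$target_id)) {
      e1 <- repdf$efficiency[repdf$target_id == tid & repdf$condition == compare[1]]
      e2 <- repdf$efficiency[repdf$target_id == tid & repdf$condition == compare[2]]
      if (length(e1) >= 2 && length(e2) >= 2) {
        tt <- .t_from_stats(mean(e1), stats::sd(e1), length(e1),
                            mean(e2), stats::sd(e2), length(e2))
        sel <- res$target_id == tid
        res$p_value[sel] <- tt["p"]
        res$t_statistic[sel] <- tt["t"]
      }
    }
  }

  structure(list(results = res, replicates = repdf, mode = mode,
                 pairing = pairing, alpha = alpha, clamp_floor = clamp_floor,
                 compare = compare, reference = reference, flags = flags,
                 call = match.call()),
            class = "tcep_quant")
}

# One replicate's full estimator chain; returns a one-row data frame, or a
# character message when the replicate must be dropped.
.replicate_chain <- function(tc, ctl, tid, cond, r, pairing, mode) {
  well <- function(df, role, rep = NULL) {
    sel <- df$role == role
    if (!is.null(rep)) sel <- sel & df$replicate == rep
    ct <- df$ct[sel]
    if (length(ct) == 0) return(NULL)       # role absent
    if (all(is.na(ct))) return(NA_real_)    # undetermined
    mean(ct, na.rm = TRUE)                  # technical replicates averaged
  }
  need <- c(ct_t = "target_region", ct_t_inter = "genomic_reference",
            ct_cas = "cas9_transcript", ct_inter = "transcript_reference")
  vals <- lapply(need, function(role) well(tc, role, r))
  for (nm in names(need)) {
    v <- vals[[nm]]
    if (is.null(v) || is.na(v)) {
      why <- if (is.null(v)) "missing" else "undetermined Ct for"
      return(sprintf("target %s (%s) replicate %d: %s %s well; replicate dropped",
                     tid, cond, r, why, need[[nm]]))
    }
  }
  if (pairing == "mean_control") {
    ct_c <- well(ctl, "target_region")
    ct_c_inter <- well(ctl, "genomic_reference")
  } else {
    ct_c <- well(ctl, "target_region", r)
    ct_c_inter <- well(ctl, "genomic_reference", r)
  }
  if (is.null(ct_c) || is.null(ct_c_inter) || is.na(ct_c) || is.na(ct_c_inter)) {
    return(sprintf("target %s (%s) replicate %d: no matching control wells; replicate dropped",
                   tid, cond, r))
  }
  abundance <- broken_dna_abundance(vals$ct_t, vals$ct_t_inter, ct_c, ct_c_inter,
                                    mode = mode)
  ddct <- attr(abundance, "ddct")
  cas9 <- cas9_abundance(vals$ct_cas, vals$ct_inter)
  data.frame(target_id = tid, condition = cond, replicate = r,
             ddct = ddct, intact_fraction = 2^(-ddct),
             broken_fraction = 1 - 2^(-ddct),
             dct_cas = vals$ct_cas - vals$ct_inter, cas9_abundance = cas9,
             efficiency = relative_cutting_efficiency(as.numeric(abundance), cas9),
             stringsAsFactors = FALSE)
}

# Pooled-variance two-sample two-sided t-test from summary statistics
# (identical to t.test(var.equal = TRUE) on the raw values).
.t_from_stats <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  if (df < 1) return(c(t = NA_real_, p = NA_real_, df = df))
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    t <- (m1 - m2) / se
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  c(t = t, p = p, df = df)
}

#' @export
print.tcep_quant <- function(x, ...) {
  cat("Cas9 cutting efficiency quantification (", x$mode, " mode, pairing: ",
      x$pairing, ")\n", sep = "")
  res <- x$results
  star <- ifelse(!is.na(res$p_value) & res$p_value < x$alpha, "*", "")
  show <- data.frame(target = res$target_id, condition = res$condition,
                     ddct = round(res$ddct, 3),
                     broken = round(res$broken_fraction, 4),
                     cas9 = signif(res$cas9_abundance, 4),
                     efficiency = signif(res$relative_efficiency, 4),
                     fold = round(res$normalized_efficiency, 3),
                     n = res$n, sig = star)
  print(show, row.names = FALSE)
  if (!all(is.na(x$reference))) {
    cat("reference (lowest efficiency, fold = 1): ", x$reference, "\n", sep = "")
  }
  if (any(nzchar(star))) cat("* p <", x$alpha, "between conditions\n")
  invisible(x)
}

#' @export
summary.tcep_quant <- function(object, ...) {
  print(object, ...)
  cat("\nreplicates per cell:\n")
  print(stats::aggregate(replicate ~ target_id + condition,
                         data = object$replicates, FUN = length),
        row.names = FALSE)
  if (length(object$flags)) {
    cat("\nflags:\n")
    cat(paste0("  - ", object$flags, collapse = "\n"), "\n")
  }
  invisible(object)
}

#' @export
coef.tcep_quant <- function(object, type = c("normalized", "relative"), ...) {
  type <- match.arg(type)
  res <- object$results
  out <- if (type == "normalized") res$normalized_efficiency else res$relative_efficiency
  nm <- res$target_id
  if (length(unique(res$condition)) > 1) nm <- paste(nm, res$condition, sep = "/")
  stats::setNames(out, nm)
}

#' @export
plot.tcep_quant <- function(x, ...) {
  res <- x$results
  h <- res$normalized_efficiency
  if (all(is.na(h))) h <- res$relative_efficiency
  nm <- res$target_id
  if (length(unique(res$condition)) > 1) nm <- paste(nm, res$condition, sep = "\n")
  up <- h * (1 + ifelse(res$relative_efficiency > 0,
                        res$sd / res$relative_efficiency, 0))
  bp <- graphics::barplot(h, names.arg = nm,
                          ylab = "cutting efficiency (fold over lowest)",
                          ylim = c(0, max(up, na.rm = TRUE) * 1.15), ...)
  graphics::segments(bp, h, bp, up)
  star <- !is.na(res$p_value) & res$p_value < x$alpha
  if (any(star)) graphics::text(bp[star], up[star], "*", pos = 3)
  invisible(x)
}

#' Quantify an in vitro Cas9 digestion experiment
#'
#' For each target, compares qPCR of the digestion products at an amplicon
#' containing the target site (`invitro_target` rows) with a reference
#' amplicon lacking it (`invitro_reference` rows), via
#' [in_vitro_efficiency()]. An undetermined target-amplicon Ct is complete
#' digestion (efficiency 1, flagged); an undetermined reference Ct is an
#' error. Negative raw efficiencies (noise) are kept in `efficiency` and
#' clamped into `[0, 1]` in `efficiency_clamped`; fold-normalisation uses
#' the clamped means floored at `clamp_floor`.
#'
#' @param records Data frame of Ct records with the in vitro roles.
#' @param clamp_floor Positive floor for fold-normalisation.
#' @return Object of class `"tcep_invitro"`: list with `results` (per
#'   target: mean raw and clamped efficiency, normalised fold, sd, n,
#'   complete-digestion flag) and `replicates`.
#' @export
tcep_invitro <- function(records, clamp_floor = 1e-6) {
  records <- validate_ct_records(records)
  vitro <- records[records$role %in% c("invitro_target", "invitro_reference"), ,
                   drop = FALSE]
  if (nrow(vitro) == 0) stop("no in vitro Ct records found", call. = FALSE)
  reps <- list()
  for (tid in unique(vitro$target_id)) {
    d <- vitro[vitro$target_id == tid, , drop = FALSE]
    for (r in sort(unique(d$replicate))) {
      a <- d$ct[d$role == "invitro_target" & d$replicate == r]
      i <- d$ct[d$role == "invitro_reference" & d$replicate == r]
      if (length(a) == 0 || length(i) == 0) {
        warning(sprintf("target %s replicate %d: missing in vitro well; replicate dropped",
                        tid, r), call. = FALSE)
        next
      }
      if (all(is.na(i))) {
        stop(sprintf("target %s replicate %d: undetermined reference Ct (no total-DNA measure)",
                     tid, r), call. = FALSE)
      }
      ct_a <- if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE)
      eff <- suppressWarnings(in_vitro_efficiency(ct_a, mean(i, na.rm = TRUE)))
      reps[[length(reps) + 1L]] <- data.frame(
        target_id = tid, replicate = r, efficiency = as.numeric(eff),
        efficiency_clamped = attr(eff, "clamped"),
        complete_digestion = attr(eff, "complete_digestion"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(reps) == 0) stop("no usable in vitro replicates", call. = FALSE)
  repdf <- do.call(rbind, reps)
  res <- do.call(rbind, lapply(split(repdf, repdf$target_id), function(d) {
    data.frame(target_id = d$target_id[1],
               efficiency = mean(d$efficiency),
               efficiency_clamped = mean(d$efficiency_clamped),
               sd = stats::sd(d$efficiency), n = nrow(d),
               complete_digestion = any(d$complete_digestion),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res$sd[is.na(res$sd)] <- 0
  norm <- normalize_to_lowest(stats::setNames(pmax(res$efficiency_clamped, clamp_floor),
                                              res$target_id))
  res$normalized_efficiency <- as.numeric(norm)
  if (any(res$complete_digestion)) {
    warning("undetermined target-amplicon Ct treated as complete digestion for some target(s)",
            call. = FALSE)
  }
  structure(list(results = res, replicates = repdf,
                 reference = attr(norm, "reference"), call = match.call()),
            class = "tcep_invitro")
}

#' @export
print.tcep_invitro <- function(x, ...) {
  cat("In vitro Cas9 digestion efficiency\n")
  res <- x$results
  show <- data.frame(target = res$target_id,
                     efficiency = round(res$efficiency, 4),
                     fold = round(res$normalized_efficiency, 3),
                     n = res$n,
                     complete = ifelse(res$complete_digestion, "yes", ""))
  print(show, row.names = FALSE)
  cat("reference (lowest efficiency, fold = 1): ", x$reference, "\n", sep = "")
  invisible(x)
}

#' Compare two quantified experiments target by target
#'
#' Builds the treatment-versus-control table used to judge whether a
#' treatment (heat, sonication, ...) changes cutting: per shared target,
#' the efficiency ratio treatment/control plus ratios of the broken-DNA
#' abundance and of Cas9 expression, and a pooled-variance Student's t-test
#' on the per-replicate efficiencies (computed from mean, sd and n, which
#' is equivalent). A treatment can raise broken DNA and Cas9 expression in
#' step while leaving their ratio — the cutting efficiency — unchanged.
#'
#' @param control,treatment `"tcep_quant"` objects or results data frames
#'   (e.g. from [read_quant_results()]).
#' @param labels Length-2 labels used in the output columns.
#' @param alpha Significance level.
#' @return Data frame of class `"tcep_comparison"`, one row per shared
#'   target: efficiency ratio, broken and Cas9 ratios when available,
#'   `t_statistic`, `p_value`, `significant`.
#' @export
tcep_compare <- function(control, treatment, labels = c("control", "treatment"),
                         alpha = 0.05) {
  a <- if (inherits(control, "tcep_quant")) control$results else control
  b <- if (inherits(treatment, "tcep_quant")) treatment$results else treatment
  shared <- intersect(a$target_id, b$target_id)
  if (length(shared) == 0) stop("no shared targets to compare", call. = FALSE)
  rows <- lapply(shared, function(tid) {
    ra <- a[a$target_id == tid, , drop = FALSE][1, ]
    rb <- b[b$target_id == tid, , drop = FALSE][1, ]
    tt <- .t_from_stats(rb$relative_efficiency, rb$sd, rb$n,
                        ra$relative_efficiency, ra$sd, ra$n)
    data.frame(target_id = tid,
               efficiency_ratio = rb$relative_efficiency / ra$relative_efficiency,
               broken_ratio = if (all(c("broken_fraction") %in% names(ra)))
                 rb$broken_fraction / ra$broken_fraction else NA_real_,
               cas9_ratio = if (all(c("cas9_abundance") %in% names(ra)))
                 rb$cas9_abundance / ra$cas9_abundance else NA_real_,
               t_statistic = tt[["t"]], p_value = tt[["p"]],
               significant = !is.na(tt[["p"]]) && tt[["p"]] < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  attr(out, "alpha") <- alpha
  class(out) <- c("tcep_comparison", "data.frame")
  out
}

#' @export
print.tcep_comparison <- function(x, ...) {
  labels <- attr(x, "labels")
  cat(sprintf("Per-target comparison: %s / %s\n", labels[2], labels[1]))
  df <- as.data.frame(x)
  df$sig <- ifelse(df$significant, "*", "")
  df$significant <- NULL
  for (cc in c("efficiency_ratio", "broken_ratio", "cas9_ratio", "t_statistic"))
    df[[cc]] <- signif(df[[cc]], 4)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  cat("* p <", attr(x, "alpha"), "\n")
  invisible(x)
}
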