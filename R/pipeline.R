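#' Pipeline configuration
#'
#' Collects every tunable stage parameter in one object. Defaults are the
#' study conventions used throughout the package: 2-s epochs, 30 epochs per
#' subject, +/-75 uV amplitude criterion, 1 Hz high-pass, the six canonical
#' bands, depth exponent 0.6 with assumed SNR 3, and 10% PLV edge trimming.
#'
#' @param epoch_len_s epoch length (s).
#' @param n_epochs epochs retained per subject.
#' @param amp_thresh_uV amplitude rejection threshold (uV).
#' @param highpass_hz high-pass cutoff (Hz).
#' @param bands band data frame (see [eeg_bands()]).
#' @param gamma inverse depth-weighting exponent.
#' @param snr assumed amplitude SNR for regularization.
#' @param edge_trim PLV edge-trim fraction.
#' @param alpha family-wise significance level.
#' @param n_boot bootstrap resamples for correlations.
#' @param seed RNG seed for stochastic stages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(epoch_len_s = 2, n_epochs = 30,
                            amp_thresh_uV = 75, highpass_hz = 1,
                            bands = eeg_bands(), gamma = 0.6, snr = 3,
                            edge_trim = 0.1, alpha = 0.05, n_boot = 5000,
                            seed = 1) {
  stopifnot(epoch_len_s > 0, n_epochs >= 1, amp_thresh_uV > 0,
            highpass_hz > 0, gamma >= 0, snr > 0,
            edge_trim >= 0, edge_trim < 0.5, alpha > 0, alpha < 1)
  structure(list(epoch_len_s = epoch_len_s, n_epochs = n_epochs,
                 amp_thresh_uV = amp_thresh_uV, highpass_hz = highpass_hz,
                 bands = bands, gamma = gamma, snr = snr,
                 edge_trim = edge_trim, alpha = alpha, n_boot = n_boot,
                 seed = seed),
            class = "pipeline_config")
}

stage <- function(name, subject, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s | stage %s] %s", subject, name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full per-subject analysis chain
#'
#' preprocess -> noise covariance -> depth-weighted minimum-norm inverse ->
#' per-band PLV connectivity -> weighted network indices. Any stage failure
#' is re-raised naming the subject and the stage.
#'
#' @param raw a [raw_recording()].
#' @param fm the [make_forward_model()] used to generate / image the data.
#' @param config a [pipeline_config()].
#' @param subject subject identifier (used in messages and output).
#' @return list with `indices` (data frame: subject, band, strength, cc,
#'   pl, efficiency), `nodal_cc` (bands x nodes matrix), `conn` (list of
#'   `conn_matrix` per band), `n_kept`.
#' @export
run_subject <- function(raw, fm, config = pipeline_config(),
                        subject = "subject") {
  es <- stage("preprocess", subject,
              preprocess_subject(raw, config$epoch_len_s, config$n_epochs,
                                 config$amp_thresh_uV, config$highpass_hz,
                                 subject = subject))
  nv <- stage("noise_covariance", subject, estimate_noise_cov(es))
  op <- stage("inverse_operator", subject,
              build_inverse_operator(fm, nv, config$gamma, config$snr))
  nodes <- stage("apply_inverse", subject, apply_inverse(op, es, fm))
  bands <- config$bands
  conn <- vector("list", nrow(bands))
  names(conn) <- bands$name
  idx <- data.frame()
  ncc <- matrix(NA_real_, nrow(bands), length(fm$node_seeds),
                dimnames = list(bands$name, NULL))
  n_ep_kept <- dim(nodes)[1]
  Xn <- matrix(aperm(nodes, c(3, 2, 1)), nrow = dim(nodes)[3])
  for (k in seq_len(nrow(bands))) {
    cm <- stage(paste0("plv_", bands$name[k]), subject,
                plv_core(Xn, length(fm$node_seeds), n_ep_kept, es$fs,
                         bands[k, ], config$edge_trim))
    ni <- stage(paste0("netmetrics_", bands$name[k]), subject,
                network_indices(cm))
    conn[[k]] <- cm
    ncc[k, ] <- ni$nodal_cc
    idx <- rbind(idx, data.frame(subject = subject, band = bands$name[k],
                                 strength = ni$strength, cc = ni$cc,
                                 pl = ni$pl, efficiency = ni$efficiency,
                                 stringsAsFactors = FALSE))
  }
  list(indices = idx, nodal_cc = ncc, conn = conn,
       n_kept = length(kept_epochs(es)))
}

#' Run the full group study
#'
#' Runs [run_subject()] for every recording, then, per band x measure
#' (6 bands x strength/CC/PL/efficiency = 24 tests), an ANCOVA with the
#' metadata covariate and a Bonferroni flag at `alpha / 24`; nodal
#' clustering coefficients are compared in `nodal_band` (theta by default,
#' where resting-state group effects concentrate) with flags at
#' `alpha / n_nodes`; and each globally flagged measure is correlated with
#' the metadata `score` via [partial_pearson_bootstrap()] within each
#' group, post-hoc pairwise contrasts included.
#'
#' @param cohort result of [simulate_cohort()], or a list with elements
#'   `recordings`, `metadata`, `fm`.
#' @param config a [pipeline_config()].
#' @param nodal_band band for the nodal analysis (default `"theta"`).
#' @param cor_covariates character vector of metadata columns used as
#'   covariates in the correlation analysis (default none).
#' @return list with `global` (24-row data frame), `nodal`, `posthoc`,
#'   `correlations`, `subject_indices`, `nodal_cc` (band-wise list of
#'   subjects x nodes matrices), `thresholds`.
#' @export
run_study <- function(cohort, config = pipeline_config(),
                      nodal_band = "theta", cor_covariates = character()) {
  meta <- cohort$metadata
  if (length(unique(meta$group)) < 2) stop("need at least 2 groups")
  fm <- cohort$fm
  n_sub <- length(cohort$recordings)
  res <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    res[[i]] <- run_subject(cohort$recordings[[i]], fm, config,
                            subject = meta$subject[i])
  }
  subject_indices <- do.call(rbind, lapply(res, `[[`, "indices"))
  bands <- config$bands$name
  measures <- c("strength", "cc", "pl", "efficiency")
  thr_global <- bonferroni_threshold(config$alpha, length(bands) * length(measures))

  global <- data.frame()
  posthoc <- list()
  for (b in bands) for (m in measures) {
    v <- subject_indices[subject_indices$band == b, m]
    cmp <- ancova_group_compare(v, meta$group, meta$covariate)
    flag <- cmp$p < thr_global
    row <- data.frame(band = b, measure = m, F = cmp$F, p = cmp$p,
                      partial_eta2 = cmp$partial_eta2, flagged = flag,
                      stringsAsFactors = FALSE)
    for (g in seq_len(nrow(cmp$group_stats))) {
      row[[paste0("mean_", cmp$group_stats$group[g])]] <- cmp$group_stats$mean[g]
      row[[paste0("sd_", cmp$group_stats$group[g])]] <- cmp$group_stats$sd[g]
    }
    global <- rbind(global, row)
    if (flag)
      posthoc[[paste(b, m, sep = ".")]] <-
        posthoc_pairwise(v, meta$group, meta$covariate)
  }

  # nodal analysis in one band
  bi <- match(nodal_band, bands)
  if (is.na(bi)) stop("unknown nodal_band")
  ncc_mat <- do.call(rbind, lapply(res, function(r) r$nodal_cc[bi, ]))
  n_nodes <- ncol(ncc_mat)
  thr_nodal <- bonferroni_threshold(config$alpha, n_nodes)
  nodal <- do.call(rbind, lapply(seq_len(n_nodes), function(j) {
    cmp <- ancova_group_compare(ncc_mat[, j], meta$group, meta$covariate)
    data.frame(node = j, band = nodal_band, F = cmp$F, p = cmp$p,
               partial_eta2 = cmp$partial_eta2, flagged = cmp$p < thr_nodal,
               stringsAsFactors = FALSE)
  }))

  # correlations of flagged global measures with the metadata score, per group
  correlations <- list()
  if ("score" %in% names(meta)) {
    flagged <- global[global$flagged, c("band", "measure")]
    Zcov <- if (length(cor_covariates)) meta[, cor_covariates, drop = FALSE]
            else NULL
    for (r in seq_len(nrow(flagged))) {
      b <- flagged$band[r]; m <- flagged$measure[r]
      v <- subject_indices[subject_indices$band == b, m]
      for (g in unique(meta$group)) {
        sel <- meta$group == g
        key <- paste(b, m, g, sep = ".")
        correlations[[key]] <- partial_pearson_bootstrap(
          v[sel], meta$score[sel],
          covariates = if (is.null(Zcov)) NULL else Zcov[sel, , drop = FALSE],
          n_boot = config$n_boot, seed = config$seed)
      }
    }
  }

  list(global = global, nodal = nodal, posthoc = posthoc,
       correlations = correlations, subject_indices = subject_indices,
       nodal_cc = ncc_mat,
       thresholds = c(global = thr_global, nodal = thr_nodal))
}
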