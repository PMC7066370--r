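# Metrological comparison against the reference system: node RMS after
# optimal rigid alignment, step-matched parameter errors, Bland-Altman
# agreement, and the two-level factorial ANOVA of the experimental design.

#' Optimal rigid alignment of the markerless series onto the reference
#'
#' Fits one Kabsch roto-translation over all valid (frame x node)
#' correspondences of the evaluation nodes and applies it to the markerless
#' series, so that trajectory errors reflect reconstruction quality rather
#' than the residual frame offset between the two systems.
#'
#' @param op Markerless `skeleton3d` (synchronized, same rate as `ref`).
#' @param ref Reference `skeleton3d`.
#' @param node_map Named character vector (markerless joint -> reference
#'   joint); defaults to the shared evaluation nodes.
#'
#' @return List with `aligned` (the transformed markerless series) and
#'   `transform` (the `rigid_transform` used).
#' @export
align_for_comparison <- function(op, ref, node_map = NULL) {
  cs <- stack_correspondences(op, ref, node_map)
  T <- kabsch(cs$P, cs$Q, from_frame = op$frame_ref, to_frame = ref$frame_ref)
  list(aligned = apply_transform(op, T), transform = T)
}

#' Per-node RMS trajectory error
#'
#' Root-mean-square 3D distance between corresponding node trajectories,
#' per node over the frames valid in both systems, reported in millimeters,
#' with the pooled mean and SD across nodes. Nodes with no valid frame are
#' reported absent (`NA`), not zero.
#'
#' @param aligned_op Aligned markerless `skeleton3d`.
#' @param ref Reference `skeleton3d` in the same frame.
#' @param node_map Named character vector as in [align_for_comparison()].
#'
#' @return List of class `node_error_report`: `per_node` (named vector,
#'   mm), `mean_mm`, `sd_mm`, `n_frames` per node.
#' @export
node_rms <- function(aligned_op, ref, node_map = NULL) {
  if (is.null(node_map)) {
    shared <- intersect(intersect(aligned_op$joints, ref$joints), eval_nodes())
    node_map <- stats::setNames(shared, shared)
  }
  n <- min(dim(aligned_op$xyz)[1], dim(ref$xyz)[1])
  rms <- stats::setNames(rep(NA_real_, length(node_map)), names(node_map))
  nfr <- stats::setNames(integer(length(node_map)), names(node_map))
  for (k in seq_along(node_map)) {
    jo <- match(names(node_map)[k], aligned_op$joints)
    jr <- match(node_map[[k]], ref$joints)
    ok <- aligned_op$valid[seq_len(n), jo] & ref$valid[seq_len(n), jr]
    nfr[k] <- sum(ok)
    if (!any(ok)) next
    d2 <- rowSums((matrix(aligned_op$xyz[seq_len(n), jo, ][ok, ], ncol = 3) -
                   matrix(ref$xyz[seq_len(n), jr, ][ok, ], ncol = 3))^2)
    rms[k] <- sqrt(mean(d2)) * 1000
  }
  structure(list(per_node = rms,
                 mean_mm = mean(rms, na.rm = TRUE),
                 sd_mm = stats::sd(rms[!is.na(rms)]),
                 n_frames = nfr),
            class = "node_error_report")
}

#' @export
print.node_error_report <- function(x, ...) {
  cat("Node RMS trajectory error (mm)\n")
  print(round(x$per_node, 1))
  cat(sprintf("mean %.1f mm, SD %.1f mm over %d nodes\n",
              x$mean_mm, x$sd_mm, sum(!is.na(x$per_node))))
  invisible(x)
}

#' Match step records of the two systems
#'
#' Greedy nearest-heel-strike-time pairing per foot with a 0.25 s
#' tolerance; steps of either system left unmatched are reported.
#'
#' @param op_steps,ref_steps Step-record data frames (see
#'   [compute_step_parameters()]), time-ordered.
#' @param tol_s Pairing tolerance in seconds.
#'
#' @return List with `pairs` (data frame of matched records, `op_` and
#'   `ref_` column prefixes), `unmatched_op`, `unmatched_ref` (row indices).
#' @export
match_steps <- function(op_steps, ref_steps, tol_s = 0.25) {
  pairs <- list()
  used_ref <- rep(FALSE, nrow(ref_steps))
  matched_op <- rep(FALSE, nrow(op_steps))
  for (foot in c("left", "right")) {
    oi <- which(op_steps$foot == foot)
    for (i in oi[order(op_steps$heel_strike_time_s[oi])]) {
      cand <- which(ref_steps$foot == foot & !used_ref)
      if (length(cand) == 0) next
      dt <- abs(ref_steps$heel_strike_time_s[cand] -
                op_steps$heel_strike_time_s[i])
      if (min(dt) > tol_s) next
      j <- cand[which.min(dt)]
      used_ref[j] <- TRUE
      matched_op[i] <- TRUE
      op_row <- op_steps[i, , drop = FALSE]
      ref_row <- ref_steps[j, , drop = FALSE]
      names(op_row) <- paste0("op_", names(op_row))
      names(ref_row) <- paste0("ref_", names(ref_row))
      pairs[[length(pairs) + 1]] <- cbind(op_row, ref_row)
    }
  }
  pairs_df <- if (length(pairs)) {
    out <- do.call(rbind, pairs); rownames(out) <- NULL
    out[order(out$op_heel_strike_time_s), ]
  } else NULL
  list(pairs = pairs_df,
       unmatched_op = which(!matched_op),
       unmatched_ref = which(!used_ref))
}

#' RMS errors of the spatio-temporal parameters over matched steps
#'
#' @param pairs Matched-pair data frame from [match_steps()].
#'
#' @return List of class `param_error_report`: `step_length_cm`,
#'   `stance_time_s`, `swing_time_s` (RMS of the per-pair differences, in
#'   the units of the names) and `n` pairs used per parameter.
#' @export
param_errors <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) < 1) stop("no matched step pairs")
  rms_of <- function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0) return(c(rms = NA_real_, n = 0))
    c(rms = sqrt(mean(d^2)), n = length(d))
  }
  sl <- rms_of((pairs$op_step_length_m - pairs$ref_step_length_m) * 100)
  st <- rms_of(pairs$op_stance_time_s - pairs$ref_stance_time_s)
  sw <- rms_of(pairs$op_swing_time_s - pairs$ref_swing_time_s)
  structure(list(step_length_cm = sl[["rms"]], stance_time_s = st[["rms"]],
                 swing_time_s = sw[["rms"]],
                 n = c(step_length = sl[["n"]], stance_time = st[["n"]],
                       swing_time = sw[["n"]])),
            class = "param_error_report")
}

#' Bland-Altman agreement statistics
#'
#' Bias (mean markerless-minus-reference difference), SD of the
#' differences, and the 95% limits of agreement `bias +/- 1.96 SD`.
#'
#' @param pairs Matched-pair data frame from [match_steps()].
#' @param parameter One of `"step_length_m"`, `"stance_time_s"`,
#'   `"swing_time_s"`.
#'
#' @return List of class `bland_altman`: `bias`, `sd`, `loa_low`,
#'   `loa_high`, `n`, `parameter` (units of the chosen parameter).
#' @export
bland_altman <- function(pairs, parameter = c("step_length_m",
                                              "stance_time_s",
                                              "swing_time_s")) {
  parameter <- match.arg(parameter)
  d <- pairs[[paste0("op_", parameter)]] - pairs[[paste0("ref_", parameter)]]
  d <- d[!is.na(d)]
  if (length(d) < 3) stop("need at least 3 matched pairs for limits of agreement")
  bias <- mean(d); s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d), parameter = parameter),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s, n=%d): bias %.4f, SD %.4f, LoA [%.4f, %.4f]\n",
              x$parameter, x$n, x$bias, x$sd, x$loa_low, x$loa_high))
  invisible(x)
}

#' Two-level factorial ANOVA of a measurement-error variable
#'
#' Ordinary least squares of the error variable on the three design factors
#' (gait direction, camera distance, video resolution) coded -1/+1, plus
#' the direction x distance interaction. Per-effect partial F statistics
#' with 1 numerator degree of freedom are tested against the residual; with
#' the balanced design of the batch generator all sums-of-squares types
#' coincide.
#'
#' @param error_table Data frame with columns `x1` (direction), `x2`
#'   (distance), `x3` (resolution), each coded -1/+1, and `xi` (the error
#'   value).
#' @param alpha Significance level for flagging (default 0.05).
#'
#' @return List of class `anova_table`: `effects` data frame (term,
#'   estimate, F, p, significant), `intercept`, `sigma2` (residual
#'   variance), `df_residual`.
#' @export
factorial_anova <- function(error_table, alpha = 0.05) {
  need <- c("x1", "x2", "x3", "xi")
  if (!all(need %in% names(error_table)))
    stop(sprintf("error table must have columns %s", paste(need, collapse = ", ")))
  if (!all(unlist(error_table[, c("x1", "x2", "x3")]) %in% c(-1, 1)))
    stop("factor levels must be coded -1/+1")
  fit <- tryCatch(
    stats::lm(xi ~ x1 + x2 + x3 + x1:x2, data = error_table),
    error = function(e) stop("singular design: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("singular design: some effects are not identifiable")
  df_res <- fit$df.residual
  if (df_res < 1) stop("no residual degrees of freedom")
  sm <- suppressWarnings(summary(fit))   # a perfect fit is handled below
  terms <- c("x1", "x2", "x3", "x1:x2")
  tt <- sm$coefficients[terms, , drop = FALSE]
  Fv <- tt[, "t value"]^2
  if (sm$sigma == 0) {
    # perfect fit (e.g. constant response): a zero effect carries no F mass
    Fv <- ifelse(abs(tt[, "Estimate"]) < 1e-12, 0, Inf)
  }
  pv <- stats::pf(Fv, 1, df_res, lower.tail = FALSE)
  effects <- data.frame(term = terms,
                        estimate = tt[, "Estimate"],
                        F = Fv, p = pv,
                        significant = pv < alpha,
                        row.names = NULL)
  structure(list(effects = effects,
                 intercept = unname(cf["(Intercept)"]),
                 sigma2 = sm$sigma^2,
                 df_residual = df_res,
                 alpha = alpha),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Factorial ANOVA (intercept %.4f, residual df %d)\n",
              x$intercept, x$df_residual))
  out <- x$effects
  out$F <- round(out$F, 2); out$p <- signif(out$p, 3)
  print(out, row.names = FALSE)
  invisible(x)
}
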