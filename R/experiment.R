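# End-to-end evaluation: preprocessing -> labeled windows -> features ->
# probe-grouped repeated stratified CV with per-fold imputation, SMOTE
# balancing and optional MRMR selection -> random-forest AUC, channel
# importance maps and prediction mutual information.

# Median imputation fitted on the training rows, applied to both splits.
impute_median <- function(x_train, x_test) {
  med <- apply(x_train, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x_train))) {
    x_train[is.na(x_train[, j]), j] <- med[j]
    x_test[is.na(x_test[, j]), j] <- med[j]
  }
  list(train = x_train, test = x_test)
}

# Cross-validated evaluation of one participant over one feature column set.
# Returns per-repeat AUC, out-of-fold predictions, and mean importances.
eval_participant_cv <- function(feat, folds_pp, cols, cfg, mrmr_k = NULL) {
  meta <- feat$meta
  X <- feat$values[, cols, drop = FALSE]
  imp_acc <- numeric(length(cols))
  imp_n <- 0L
  preds <- NULL
  for (r in unique(folds_pp$rep)) {
    fr <- folds_pp[folds_pp$rep == r, , drop = FALSE]
    for (f in sort(unique(fr$fold))) {
      train_probes <- fr$probe_id[fr$fold != f]
      test_probes <- fr$probe_id[fr$fold == f]
      tr <- meta$probe_id %in% train_probes
      te <- meta$is_test & meta$probe_id %in% test_probes
      if (!any(te)) next
      imp <- impute_median(X[tr, , drop = FALSE], X[te, , drop = FALSE])
      fold_seed <- derive_seed(cfg$seed, meta$participant_id[1], r, f)
      bal <- tryCatch(
        suppressWarnings(smote_balance(imp$train, meta$label[tr],
                                       k = cfg$smote_k, seed = fold_seed)),
        error = function(e) NULL)
      if (is.null(bal)) {
        warning(sprintf("fold %d (rep %d) skipped: %s", f, r,
                        "degenerate training split"), call. = FALSE)
        next
      }
      xtr <- bal$x
      xte <- imp$test
      sel <- seq_len(ncol(xtr))
      if (!is.null(mrmr_k) && mrmr_k < ncol(xtr)) {
        sel <- mrmr_select(xtr, bal$y, mrmr_k)
        xtr <- xtr[, sel, drop = FALSE]
        xte <- xte[, sel, drop = FALSE]
      }
      fit <- fit_predict_rf(xtr, bal$y, xte, num_trees = cfg$num_trees,
                            seed = fold_seed)
      imp_full <- numeric(length(cols))
      imp_full[sel] <- fit$importance
      imp_acc <- imp_acc + imp_full
      imp_n <- imp_n + 1L
      preds <- rbind(preds, data.frame(
        probe_id = meta$probe_id[te], rep = r,
        score = fit$scores, label = meta$label[te],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(preds)) return(NULL)
  auc_by_rep <- vapply(split(preds, preds$rep), function(d) {
    if (length(unique(d$label)) < 2) return(NA_real_)
    auc(d$score, d$label)
  }, numeric(1))
  if (all(is.na(auc_by_rep))) return(NULL)  # no scorable repeat
  preds$pred <- ifelse(preds$score >= 0.5, "MW", "nonMW")
  list(auc = mean(auc_by_rep, na.rm = TRUE),
       auc_by_rep = auc_by_rep,
       importance = imp_acc / max(imp_n, 1L),
       preds = preds)
}

# Preprocess, window and featurize one session.
prepare_participant <- function(session, preproc, params, families) {
  clean <- preprocess_session(session, preproc)
  es <- build_epoch_set(clean)
  suppressWarnings(extract_feature_matrix(es, params, families))
}

#' Run the full detection experiment on a cohort
#'
#' Applies the whole pipeline to a list of raw sessions and evaluates
#' mind-wandering detection with probe-grouped repeated stratified
#' cross-validation. Training always uses the class-dependent augmentation
#' windows of the training probes (SMOTE-balanced); testing always scores
#' the single pre-probe window of the held-out probes.
#'
#' @param cohort list of `mw_session` objects (e.g. [generate_cohort()]).
#' @param preproc a [preproc_config()].
#' @param params a [complexity_params()].
#' @param cv a [cv_config()].
#' @param families feature families to compute.
#' @param scales_analysis multiscale scales used in family-level and pooled
#'   analyses (default 1:10; the per-scale sweep still covers all computed
#'   scales).
#' @param mrmr_sweep_k feature counts for the MRMR sweep.
#' @param analyses which result blocks to compute: any of `"family"`,
#'   `"scale"`, `"mrmr"`, `"channel"`, `"importance"`, `"prediction_mi"`.
#' @param min_mw_prop participant inclusion threshold on the MW probe
#'   proportion (default 0.10).
#' @param verbose print progress.
#' @return object of class `mw_eval_report`; a list of data.frames
#'   (`auc_by_family`, `auc_by_scale`, `mrmr_sweep`, `auc_by_channel`,
#'   `channel_importance`, `prediction_mi`) plus the participant filter
#'   outcome and the configuration used.
#' @export
run_experiment <- function(cohort,
                           preproc = preproc_config(),
                           params = complexity_params(),
                           cv = cv_config(),
                           families = FEATURE_FAMILIES,
                           scales_analysis = 1:10,
                           mrmr_sweep_k = c(10, 20, 30, 60, 120, 240),
                           analyses = c("family", "scale", "mrmr", "channel",
                                        "importance", "prediction_mi"),
                           min_mw_prop = 0.10,
                           verbose = FALSE) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  feats <- list()
  probe_tbl <- NULL
  for (id in names(cohort)) {
    if (verbose) message("preparing ", id)
    f <- prepare_participant(cohort[[id]], preproc, params, families)
    feats[[id]] <- f
    pr <- unique(f$meta[, c("participant_id", "probe_id", "label")])
    probe_tbl <- rbind(probe_tbl, pr)
  }
  filt <- filter_participants(probe_tbl, min_mw_prop)
  probe_tbl <- probe_tbl[probe_tbl$participant_id %in% filt$kept, , drop = FALSE]
  folds <- probe_grouped_folds(probe_tbl, cv)
  pids <- unique(folds$participant_id)

  restricted_cols <- function(feat, fams) {
    d <- feat$descriptors
    keep_scale <- d$scale_or_band %in%
      c(paste0("s", scales_analysis), names(params$bands), "")
    which(d$family %in% fams & keep_scale)
  }

  report <- list(participants = pids, filter = filt,
                 config = list(preproc = preproc, params = params, cv = cv,
                               families = families,
                               scales_analysis = scales_analysis))

  family_runs <- NULL
  if (any(c("family", "importance", "prediction_mi") %in% analyses)) {
    family_runs <- list()
    auc_fam <- NULL
    for (fam in families) {
      if (verbose) message("family ", fam)
      runs <- list()
      for (pid in pids) {
        res <- eval_participant_cv(feats[[pid]],
                                   folds[folds$participant_id == pid, ],
                                   restricted_cols(feats[[pid]], fam), cv)
        if (is.null(res)) next
        runs[[pid]] <- res
        auc_fam <- rbind(auc_fam, data.frame(participant_id = pid,
                                             family = fam, auc = res$auc))
      }
      family_runs[[fam]] <- runs
    }
    report$auc_by_family <- auc_fam
  }

  if ("scale" %in% analyses) {
    ms_fams <- intersect(families, c("MSE", "MPE", "MDE"))
    auc_scale <- NULL
    for (fam in ms_fams) {
      for (s in params$scales) {
        for (pid in pids) {
          cols <- feature_columns(feats[[pid]], family = fam,
                                  scale_or_band = paste0("s", s))
          res <- eval_participant_cv(feats[[pid]],
                                     folds[folds$participant_id == pid, ],
                                     cols, cv)
          if (is.null(res)) next
          auc_scale <- rbind(auc_scale, data.frame(
            participant_id = pid, family = fam, scale = s, auc = res$auc))
        }
      }
    }
    report$auc_by_scale <- auc_scale
  }

  if ("mrmr" %in% analyses) {
    sweep <- NULL
    for (pid in pids) {
      cols <- restricted_cols(feats[[pid]], families)
      for (K in mrmr_sweep_k) {
        if (K > length(cols)) next
        res <- eval_participant_cv(feats[[pid]],
                                   folds[folds$participant_id == pid, ],
                                   cols, cv, mrmr_k = K)
        if (is.null(res)) next
        sweep <- rbind(sweep, data.frame(participant_id = pid,
                                         family = "All", k = K,
                                         auc = res$auc))
      }
    }
    report$mrmr_sweep <- sweep
  }

  if ("channel" %in% analyses) {
    auc_ch <- NULL
    for (pid in pids) {
      for (ch in feats[[pid]]$descriptors$channel |> unique()) {
        cols <- intersect(restricted_cols(feats[[pid]], families),
                          feature_columns(feats[[pid]], channel = ch))
        res <- eval_participant_cv(feats[[pid]],
                                   folds[folds$participant_id == pid, ],
                                   cols, cv)
        if (is.null(res)) next
        auc_ch <- rbind(auc_ch, data.frame(participant_id = pid,
                                           channel = ch, auc = res$auc))
      }
    }
    report$auc_by_channel <- auc_ch
  }

  if ("importance" %in% analyses && length(family_runs)) {
    imp <- NULL
    for (fam in names(family_runs)) {
      runs <- family_runs[[fam]]
      if (!length(runs)) next
      pid1 <- names(runs)[1]
      desc <- feats[[pid1]]$descriptors[restricted_cols(feats[[pid1]], fam), ]
      imp_mat <- vapply(runs, function(r) r$importance,
                        numeric(nrow(desc)))
      ch_imp <- channel_importance(rowMeans(imp_mat), desc)
      imp <- rbind(imp, data.frame(family = fam, channel = names(ch_imp),
                                   importance = as.numeric(ch_imp)))
    }
    report$channel_importance <- imp
  }

  if ("prediction_mi" %in% analyses && length(family_runs) >= 1) {
    fams <- names(family_runs)
    mi <- matrix(NA_real_, length(fams), length(fams),
                 dimnames = list(fams, fams))
    for (i in seq_along(fams)) for (j in seq_len(i)) {
      vals <- c()
      for (pid in pids) {
        ra <- family_runs[[fams[i]]][[pid]]
        rb <- family_runs[[fams[j]]][[pid]]
        if (is.null(ra) || is.null(rb)) next
        key <- paste(ra$preds$probe_id, ra$preds$rep)
        keyb <- paste(rb$preds$probe_id, rb$preds$rep)
        common <- intersect(key, keyb)
        if (length(common) < 2) next
        pa <- ra$preds$pred[match(common, key)]
        pb <- rb$preds$pred[match(common, keyb)]
        vals <- c(vals, prediction_mutual_information(pa, pb))
      }
      mi[i, j] <- mi[j, i] <- mean(vals)
    }
    report$prediction_mi <- mi
  }

  structure(report, class = "mw_eval_report")
}

#' @export
print.mw_eval_report <- function(x, ...) {
  cat(sprintf("<mw_eval_report> %d participants", length(x$participants)))
  if (length(x$filter$removed))
    cat(sprintf(" (%d excluded below the MW-proportion threshold)",
                length(x$filter$removed)))
  cat("\n")
  if (!is.null(x$auc_by_family)) {
    agg <- stats::aggregate(auc ~ family, x$auc_by_family, mean)
    cat("mean AUC by family:\n")
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  %-4s %.3f\n", agg$family[i], agg$auc[i]))
  }
  if (!is.null(x$mrmr_sweep)) {
    agg <- stats::aggregate(auc ~ k, x$mrmr_sweep, mean)
    cat("pooled-feature AUC by MRMR feature count:\n")
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  k=%-4d %.3f\n", agg$k[i], agg$auc[i]))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' CSV tables (one per result block) plus a JSON manifest with the full
#' configuration and participant filter outcome.
#'
#' @param report an `mw_eval_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  tables <- c("auc_by_family", "auc_by_scale", "mrmr_sweep",
              "auc_by_channel", "channel_importance")
  for (tb in tables) {
    if (is.null(report[[tb]])) next
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(report[[tb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$prediction_mi)) {
    p <- file.path(dir, "prediction_mi.csv")
    utils::write.csv(as.data.frame(report$prediction_mi), p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    participants = report$participants,
    excluded = report$filter$removed,
    mw_proportions = as.list(report$filter$proportions),
    config = report$config
  ), mp, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(paths, mp))
}
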