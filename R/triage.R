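#' Extract classifier features from folded hairpin windows
#'
#' Computes the documented, fixed-order feature vector used by the triage
#' stage, from sequence and MFE structure alone (scores are therefore
#' invariant to a window's genomic coordinate): length, GC fraction, MFE,
#' MFE per nucleotide, pair count, pairing fraction (2 * pairs / length),
#' longest helix (maximal run of stacked pairs), terminal-loop size (first
#' hairpin loop; 0 when none), stem asymmetry (absolute difference between
#' unpaired counts 5' and 3' of the first hairpin loop), and the 16
#' dinucleotide frequencies (columns `dn_AA` .. `dn_TT`).
#'
#' @param windows A `data.frame` with columns `seq`, `structure`, `mfe`
#'   (e.g. from [scan_sequence()]).
#' @return A numeric `data.frame`, one row per window, columns in the fixed
#'   order above.
#' @export
extract_features <- function(windows) {
  stopifnot(all(c("seq", "structure", "mfe") %in% names(windows)))
  bases <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(bases, bases, paste0))
  one <- function(seq, db, mfe) {
    seq <- chartr("U", "T", toupper(seq))
    n <- nchar(seq)
    chars <- strsplit(seq, "")[[1]]
    pt <- pair_table(db)
    npairs <- sum(!is.na(pt)) / 2L
    # longest run of stacked pairs
    opens <- which(!is.na(pt) & pt > seq_len(n))
    longest <- 0L
    run <- 0L
    for (i in opens) {
      if (run > 0L && (i - 1L) %in% opens && pt[i] == pt[i - 1L] - 1L) {
        run <- run + 1L
      } else run <- 1L
      longest <- max(longest, run)
    }
    # first hairpin loop: maximal run of unpaired positions whose flanks pair
    loop_start <- NA_integer_
    loop_size <- 0L
    for (i in opens) {
      j <- pt[i]
      if (nrow(loop_children(pt, i, j)) == 0L) {
        loop_start <- i + 1L
        loop_size <- j - i - 1L
        break
      }
    }
    unp <- is.na(pt)
    if (is.na(loop_start)) {
      mid <- n %/% 2L
      asym <- abs(sum(unp[seq_len(mid)]) - sum(unp[seq(mid + 1L, n)]))
    } else {
      asym <- abs(sum(unp[seq_len(loop_start - 1L)]) -
                    sum(unp[seq(loop_start + loop_size, n)]))
    }
    dn <- substring(seq, 1:(n - 1), 2:n)
    dn_freq <- as.numeric(table(factor(dn, levels = dinucs))) / (n - 1)
    c(length = n,
      gc = sum(chars %in% c("G", "C")) / n,
      mfe = mfe,
      mfe_per_nt = mfe / n,
      n_pairs = npairs,
      pairing_fraction = 2 * npairs / n,
      longest_helix = longest,
      terminal_loop = loop_size,
      stem_asymmetry = asym,
      setNames(dn_freq, paste0("dn_", dinucs)))
  }
  feats <- t(mapply(one, windows$seq, windows$structure, windows$mfe))
  rownames(feats) <- NULL
  as.data.frame(feats)
}

#' Train the hairpin triage classifier
#'
#' Supervised stand-in for the high-confidence hairpin triage stage: a
#' logistic regression on the [extract_features()] vector, trained on
#' labeled positive (real pre-miRNA hairpin) and negative windows.  The
#' model seam is deliberately thin — candidates can equally be exported to,
#' and scores imported from, any external classifier.  Reports seeded
#' k-fold cross-validated accuracy.
#'
#' @param pos,neg Window `data.frame`s (columns `seq`, `structure`, `mfe`)
#'   or ready-made feature `data.frame`s; at least 10 examples each.
#' @param threshold Decision threshold on the score in `[0, 1]`.
#' @param nfolds Cross-validation folds.
#' @param seed RNG seed for fold assignment (model fitting itself is
#'   deterministic).
#' @return A list of class `triage_model`: `fit`, `features` (schema),
#'   `threshold`, `cv_accuracy`, `n_pos`, `n_neg`, `seed`.
#' @export
train_triage <- function(pos, neg, threshold = 0.5, nfolds = 5L, seed = 1L) {
  as_feats <- function(x) if ("structure" %in% names(x)) extract_features(x) else x
  fp <- as_feats(pos)
  fn <- as_feats(neg)
  if (nrow(fp) < 10L || nrow(fn) < 10L)
    stop("need at least 10 positive and 10 negative training windows")
  if (!identical(names(fp), names(fn))) stop("feature schema mismatch")
  x <- rbind(fp, fn)
  y <- c(rep(1L, nrow(fp)), rep(0L, nrow(fn)))
  if (length(unique(y)) < 2L) stop("degenerate single-class training input")
  # drop constant columns (undefined coefficients otherwise)
  keep <- vapply(x, function(col) stats::var(col) > 0, logical(1))
  dat <- cbind(x[, keep, drop = FALSE], .label = y)
  fit_fun <- function(d) {
    suppressWarnings(glm(.label ~ ., data = d, family = binomial()))
  }
  cv_acc <- with_seed(seed, {
    fold <- sample(rep_len(seq_len(nfolds), nrow(dat)))
    hits <- vapply(seq_len(nfolds), function(k) {
      f <- fit_fun(dat[fold != k, , drop = FALSE])
      p <- suppressWarnings(
        predict(f, newdata = dat[fold == k, , drop = FALSE], type = "response"))
      sum((p >= 0.5) == (dat$.label[fold == k] == 1L))
    }, numeric(1))
    sum(hits) / nrow(dat)
  })
  fit <- fit_fun(dat)
  structure(list(fit = fit, features = names(fp)[keep],
                 all_features = names(fp), threshold = threshold,
                 cv_accuracy = cv_acc, n_pos = nrow(fp), n_neg = nrow(fn),
                 seed = seed),
            class = "triage_model")
}

#' @export
print.triage_model <- function(x, ...) {
  cat("triage model: logistic regression on", length(x$features),
      "features\n  trained on", x$n_pos, "positives /", x$n_neg,
      "negatives (seed", paste0(x$seed, ")"),
      sprintf("\n  cross-validated accuracy %.3f, threshold %.2f\n",
              x$cv_accuracy, x$threshold))
  invisible(x)
}

#' Score and flag candidate windows with a trained triage model
#'
#' Annotates each candidate with a score in `[0, 1]` and a keep/drop flag
#' at the model threshold.  A `threshold` of 0 keeps everything, so the
#' pipeline can run with triage effectively disabled; disabling triage
#' always yields a superset of the triage-enabled atlas.
#'
#' @param model A [train_triage()] model.
#' @param candidates Window `data.frame` (columns `seq`, `structure`,
#'   `mfe`) or feature `data.frame` with the training schema.
#' @param threshold Override of the model's decision threshold.
#' @return `candidates` with `triage_score` and `triage_keep` columns.
#' @export
apply_triage <- function(model, candidates, threshold = model$threshold) {
  if (nrow(candidates) == 0L) {
    candidates$triage_score <- numeric(0)
    candidates$triage_keep <- logical(0)
    return(candidates)
  }
  feats <- if ("structure" %in% names(candidates))
    extract_features(candidates)
  else candidates
  if (!identical(names(feats), model$all_features))
    stop("feature schema mismatch between model and candidates")
  p <- suppressWarnings(
    predict(model$fit, newdata = feats[, model$features, drop = FALSE],
            type = "response"))
  candidates$triage_score <- unname(p)
  candidates$triage_keep <- unname(p >= threshold)
  candidates
}
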