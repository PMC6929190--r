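#' One-vs-one SVM biometric identification
#'
#' Multiclass identification over cardiac feature vectors with one
#' binary RBF-kernel support vector machine per unordered subject pair
#' (`n(n-1)/2` classifiers for `n` subjects — 253 for a 23-subject
#' cohort) and majority voting at prediction time. Features are
#' normalized with statistics fitted on the training set only; the
#' penalty `C` and kernel width `gamma` are chosen by stratified
#' cross-validated grid search.
#'
#' @name identification
NULL

fit_normalization <- function(x, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (method == "minmax") {
    lo <- apply(x, 2L, min)
    hi <- apply(x, 2L, max)
    scale <- hi - lo
    scale[scale < 1e-12] <- 1
    list(method = method, shift = lo, scale = scale)
  } else {
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    sdv[sdv < 1e-12] <- 1
    list(method = method, shift = mu, scale = sdv)
  }
}

apply_normalization <- function(x, norm) {
  sweep(sweep(x, 2L, norm$shift, `-`), 2L, norm$scale, `/`)
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    drop_cols <- intersect(c("subject", "beat", "label"), names(features))
    x <- as.matrix(features[, setdiff(names(features), drop_cols), drop = FALSE])
  } else x <- as.matrix(features)
  storage.mode(x) <- "double"
  x
}

stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

train_pairwise <- function(x, labels, C, gamma) {
  classes <- levels(labels)
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  classifiers <- lapply(pairs, function(pr) {
    sel <- labels %in% pr
    e1071::svm(x[sel, , drop = FALSE], factor(labels[sel], levels = pr),
               type = "C-classification", kernel = "radial",
               cost = C, gamma = gamma, scale = FALSE)
  })
  names(classifiers) <- vapply(pairs, paste, character(1L), collapse = "|")
  list(pairs = pairs, classifiers = classifiers)
}

predict_votes <- function(pairwise, classes, x) {
  votes <- matrix(0L, nrow = nrow(x), ncol = length(classes),
                  dimnames = list(NULL, classes))
  for (i in seq_along(pairwise$classifiers)) {
    pred <- as.character(stats::predict(pairwise$classifiers[[i]], x))
    for (cl in pairwise$pairs[[i]])
      votes[, cl] <- votes[, cl] + (pred == cl)
  }
  votes
}

#' Train a one-vs-one RBF-SVM identifier
#'
#' @param features data frame of feature columns (columns `subject`,
#'   `beat`, `label` are dropped automatically) or a numeric matrix.
#' @param labels class label per row (factor or character).
#' @param cv_folds stratified cross-validation folds for the grid search
#'   (default 10; reduced automatically if a class has fewer samples).
#' @param C_grid,gamma_grid candidate penalty / RBF width values.
#' @param normalization `"minmax"` (rescale each feature to \[0, 1\]) or
#'   `"zscore"`.
#' @param seed RNG seed for fold assignment.
#' @return a `heartcs_identifier`: pairwise classifiers, chosen `C` and
#'   `gamma`, normalization statistics, class labels and the CV table.
#' @export
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' x[11:20, 1] <- x[11:20, 1] + 10
#' m <- train_identifier(x, rep(c("a", "b"), each = 10),
#'                       cv_folds = 2, C_grid = 1, gamma_grid = 0.5)
#' length(m$pairwise$classifiers)  # 1 classifier for 2 classes
train_identifier <- function(features, labels, cv_folds = 10,
                             C_grid = 10^(-2:3), gamma_grid = 10^(-3:1),
                             normalization = c("minmax", "zscore"),
                             seed = 1L) {
  x <- feature_matrix(features)
  labels <- factor(as.character(labels))
  if (nrow(x) != length(labels))
    stop("features and labels must have matching rows")
  if (nlevels(labels) < 2L) stop("at least two classes are required")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("class with fewer than 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  norm <- fit_normalization(x, match.arg(normalization))
  xn <- apply_normalization(x, norm)

  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  if (nrow(grid) > 1L) {
    k <- max(2L, min(cv_folds, min(counts)))
    fold <- stratified_folds(labels, k, seed)
    grid$accuracy <- NA_real_
    for (g in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(k)) {
        tr <- fold != f
        if (length(unique(labels[tr])) < nlevels(labels)) next
        pw <- train_pairwise(xn[tr, , drop = FALSE], droplevels(labels[tr]),
                             grid$C[g], grid$gamma[g])
        v <- predict_votes(pw, levels(labels), xn[!tr, , drop = FALSE])
        pred <- colnames(v)[max.col(v, ties.method = "first")]
        correct <- correct + sum(pred == as.character(labels)[!tr])
      }
      grid$accuracy[g] <- correct / length(labels)
    }
    best <- which.max(grid$accuracy)
  } else {
    grid$accuracy <- NA_real_
    best <- 1L
  }
  C <- grid$C[best]
  gamma <- grid$gamma[best]
  pairwise <- train_pairwise(xn, labels, C, gamma)
  structure(
    list(pairwise = pairwise, classes = levels(labels), C = C,
         gamma = gamma, normalization = norm, cv_table = grid,
         n_features = ncol(x)),
    class = "heartcs_identifier"
  )
}

#' @export
print.heartcs_identifier <- function(x, ...) {
  cat(sprintf(
    "<heartcs_identifier> %d classes, %d pairwise RBF-SVMs (C=%g, gamma=%g)\n",
    length(x$classes), length(x$pairwise$classifiers), x$C, x$gamma))
  invisible(x)
}

#' Identify subjects by majority vote
#'
#' Every pairwise classifier casts one vote per sample; the class with
#' the most votes wins. Ties are broken toward the lexicographically
#' first class label, with a warning.
#'
#' @param model a [train_identifier()] model.
#' @param features feature rows to classify (same columns as training).
#' @return data frame with `label` (predicted class) and `top_votes`;
#'   the full vote tally (rows = samples, columns = classes, each row
#'   summing to `n(n-1)/2`) is in attribute `"votes"`.
#' @export
identify <- function(model, features) {
  stopifnot(inherits(model, "heartcs_identifier"))
  x <- feature_matrix(features)
  if (ncol(x) != model$n_features)
    stop("feature count differs from training (", model$n_features, ")")
  xn <- apply_normalization(x, model$normalization)
  votes <- predict_votes(model$pairwise, model$classes, xn)
  winner <- integer(nrow(votes))
  for (i in seq_len(nrow(votes))) {
    mx <- max(votes[i, ])
    cand <- which(votes[i, ] == mx)
    if (length(cand) > 1L)
      warning("vote tie for sample ", i, "; choosing lowest class label")
    winner[i] <- cand[1L]
  }
  out <- data.frame(label = model$classes[winner],
                    top_votes = votes[cbind(seq_len(nrow(votes)), winner)])
  attr(out, "votes") <- votes
  out
}

#' End-to-end recognition experiment
#'
#' Generates a synthetic multi-subject ECG population, extracts per-window
#' feature vectors from the original signals and from their compressed-
#' sensing reconstructions (DCT domain, Gaussian ensemble, SWAMP), trains
#' the identifier on original training windows, and reports test accuracy
#' before reconstruction, after reconstruction, and their difference —
#' the operational check that compression does not alter identity
#' information.
#'
#' @param n_subjects cohort size (default 23).
#' @param n_train,n_test feature windows ("sets of features") per subject
#'   (default 3 each).
#' @param window_n samples per window (default 1024, giving two complete
#'   beats at 500 Hz and 75 bpm).
#' @param fs sampling rate (Hz).
#' @param heart_rate base heart rate of the population (bpm).
#' @param jitter relative morphology jitter across subjects.
#' @param white_sd per-window additive noise sd (mV); distinct seeded
#'   draws make windows of one subject differ.
#' @param compression_ratio M/N for the sensing stage.
#' @param swamp SWAMP solver settings ([swamp_config()]).
#' @param C_grid,gamma_grid,cv_folds identifier grid-search settings
#'   (modest defaults keep the harness quick).
#' @param seed global seed; all stage seeds derive from it.
#' @return list with `accuracy_before`, `accuracy_after`, `difference`,
#'   `mean_mr` (mean matching rate of the test reconstructions), the
#'   trained `model`, and the per-window prediction table `details`.
#' @export
recognition_experiment <- function(n_subjects = 23, n_train = 3, n_test = 3,
                                   window_n = 1024, fs = 500,
                                   heart_rate = 75, jitter = 0.1,
                                   white_sd = 0.01,
                                   compression_ratio = 0.7,
                                   swamp = swamp_config(),
                                   C_grid = c(1, 10, 100),
                                   gamma_grid = c(0.01, 0.1, 1),
                                   cv_folds = 3, seed = 1L) {
  base <- beat_template("ecg", heart_rate = heart_rate)
  pop <- make_population(n_subjects, base = base, jitter = jitter,
                         seed = stage_seed(seed, "population"))
  domain <- dct_domain(window_n)
  ensemble <- gaussian_ensemble(window_n, compression_ratio,
                                seed = stage_seed(seed, "sensing"))
  duration <- window_n / fs

  make_window <- function(subject, tpl, w) {
    ns <- noise_spec(white_sd = white_sd,
                     seed = stage_seed(seed, paste0(subject, "-w", w)))
    ecg <- make_ecg(tpl, duration = duration, fs = fs, noise = ns)
    ecg$signal$subject_id <- subject
    ecg$signal
  }
  window_features <- function(sig) {
    fid <- detect_ecg_fiducials(sig)
    extract_features(fid, sig, aggregate = "mean")
  }

  train_rows <- list(); test_rows <- list(); recon_rows <- list()
  mrs <- numeric(0)
  for (s in names(pop)) {
    tpl <- pop[[s]]
    for (w in seq_len(n_train))
      train_rows[[length(train_rows) + 1L]] <-
        window_features(make_window(s, tpl, w))
    for (w in seq_len(n_test)) {
      sig <- make_window(s, tpl, n_train + w)
      test_rows[[length(test_rows) + 1L]] <- window_features(sig)
      obs <- sense(ensemble, sig$samples)
      rec <- cs_reconstruct(obs, domain, algorithm = "swamp", config = swamp)
      mrs <- c(mrs, matching_rate(sig$samples, rec$x_hat))
      rsig <- signal(rec$x_hat, fs = fs, subject_id = s, kind = "ecg")
      recon_rows[[length(recon_rows) + 1L]] <- window_features(rsig)
    }
  }
  train_feat <- do.call(rbind, train_rows)
  test_feat <- do.call(rbind, test_rows)
  recon_feat <- do.call(rbind, recon_rows)

  model <- train_identifier(train_feat, train_feat$subject,
                            cv_folds = cv_folds, C_grid = C_grid,
                            gamma_grid = gamma_grid,
                            seed = stage_seed(seed, "svm"))
  pred_before <- identify(model, test_feat)
  pred_after <- identify(model, recon_feat)
  truth <- test_feat$subject
  acc_before <- mean(pred_before$label == truth)
  acc_after <- mean(pred_after$label == truth)
  list(accuracy_before = acc_before, accuracy_after = acc_after,
       difference = acc_after - acc_before, mean_mr = mean(mrs),
       model = model,
       details = data.frame(subject = truth,
                            before = pred_before$label,
                            after = pred_after$label,
                            stringsAsFactors = FALSE))
}
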