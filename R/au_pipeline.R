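# AU-specific coefficient learning, classification and synthesis.
#
# The deformation coefficients of a single fit mix identity and expression.
# The two-step procedure decouples them: fit the average face to a
# subject's neutral scan (identity coefficients, fitted neutral s_n),
# resample s_n onto the actual scan surface (s_hat_n), then fit s_hat_n to
# the subject's expressive scan — the new coefficients alpha_e encode only
# the AU motion.  Collected over subjects, those coefficients train a
# One-vs-Rest RBF-SVM and, averaged per AU, act as prototypes that
# synthesize the AU on any registered face.

#' Fit the identity component to a neutral scan
#'
#' Deforms the average model onto a subject's neutral scan, returning the
#' fitted neutral shape and the aggregated identity coefficients.
#'
#' @param model an `slc_model`.
#' @param neutral_scan a [trimesh()] of the subject in neutral expression.
#' @param opts fitting options, see [fit_model()].
#' @return list with `s_n` (fitted [registered_shape()]), `alpha_id`
#'   (aggregated identity coefficients) and `fit` (the full
#'   `fit_result`).
#' @export
fit_identity <- function(model, neutral_scan, opts = list()) {
  fr <- fit_model(model, neutral_scan, base = NULL, opts = opts)
  list(s_n = fr$deformed, alpha_id = fr$alpha, fit = fr)
}

#' Resample a fitted neutral onto the raw scan surface
#'
#' Replaces every vertex of the fitted neutral `s_n` by its
#' nearest-neighbour vertex in the raw scan, yielding a neutral model
#' `s_hat_n` on the template topology whose every point is an exact scan
#' vertex — the actual target surface rather than its approximation.
#'
#' @param s_n fitted neutral [registered_shape()], aligned to the scan.
#' @param neutral_scan the raw neutral [trimesh()].
#' @return a [registered_shape()] on the same topology.
#' @export
resample_neutral <- function(s_n, neutral_scan) {
  tm <- as_point_matrix(neutral_scan)
  if (nrow(tm) < 1L) stop("neutral scan is empty")
  snap <- correspond(s_n, tm)
  registered_shape(flatten_points(snap), s_n$topology_id)
}

nose_tip_of <- function(x, vertex = NULL) {
  if (inherits(x, "trimesh") && !is.null(x$landmarks) &&
      "nose_tip" %in% rownames(x$landmarks)) {
    return(x$landmarks["nose_tip", ])
  }
  pts <- as_point_matrix(x)
  if (!is.null(vertex)) return(pts[vertex, ])  # known template vertex index
  pts[which.max(pts[, 3L]), ]   # proxy: maximal-z vertex in canonical frame
}

#' Extract AU-specific deformation coefficients
#'
#' Second step of the decoupling: aligns the expressive scan to the
#' resampled neutral (nose-tip translation, then rigid ICP), fits the
#' model with the neutral as base shape, and aggregates the per-iteration
#' coefficients into a single `alpha_e` vector.
#'
#' @param model an `slc_model`.
#' @param s_hat_n resampled neutral from [resample_neutral()].
#' @param expressive_scan a [trimesh()] of the same subject with an AU
#'   active; its `label` becomes the record's AU label.  Needs a
#'   `nose_tip` landmark or the maximal-z proxy is used.
#' @param opts fitting options, see [fit_model()]; `aggregate` selects the
#'   per-iteration aggregation strategy (default `"mean"`); `nose_vertex`
#'   gives the template vertex index of the nose tip, used to locate it on
#'   `s_hat_n` (fallback: maximal-z proxy).
#' @return an `au_record`: list with `subject_id`, `au_label`, `alpha_e`,
#'   `n_iterations`, `model_id`.
#' @export
extract_au_coefficients <- function(model, s_hat_n, expressive_scan,
                                    opts = list()) {
  shift <- nose_tip_of(s_hat_n, vertex = opts$nose_vertex) -
    nose_tip_of(expressive_scan)
  pts <- sweep(as_point_matrix(expressive_scan), 2L, shift, "+")
  lm <- expressive_scan$landmarks
  if (!is.null(lm)) lm <- sweep(lm, 2L, shift, "+")
  aligned <- trimesh(pts, landmarks = lm,
                     subject_id = expressive_scan$subject_id,
                     label = expressive_scan$label)
  opts$icp <- opts$icp %||% TRUE          # rigid ICP after nose-tip alignment
  fr <- fit_model(model, aligned, base = s_hat_n, opts = opts)
  structure(
    list(subject_id = expressive_scan$subject_id %||% NA_character_,
         au_label = expressive_scan$label %||% NA_character_,
         alpha_e = fr$alpha, n_iterations = fr$iterations,
         model_id = model$topology_id, fit = fr),
    class = "au_record"
  )
}

#' Aggregate per-iteration coefficient vectors
#'
#' The iterative fit yields one coefficient vector per iteration; the
#' element-wise average cancels the near zero-mean contributions of sensor
#' noise and slight misalignment while keeping the AU motion.
#'
#' @param alphas non-empty list of equal-length numeric vectors.
#' @param strategy `"mean"` (element-wise average, default), `"max"`
#'   (element-wise signed value of maximal magnitude), `"first"`, or
#'   `"threshold"` (mean after zeroing entries below `t` in magnitude).
#' @param t magnitude threshold for `strategy = "threshold"`.
#' @return aggregated coefficient vector.
#' @export
aggregate_coefficients <- function(alphas,
                                   strategy = c("mean", "max", "first", "threshold"),
                                   t = 1e-3) {
  strategy <- match.arg(strategy)
  if (!length(alphas)) stop("cannot aggregate an empty coefficient list")
  A <- do.call(rbind, alphas)
  switch(strategy,
    mean = colMeans(A),
    max = A[cbind(max.col(t(abs(A)), ties.method = "first"), seq_len(ncol(A)))],
    first = alphas[[1L]],
    threshold = {
      A[abs(A) < t] <- 0
      colMeans(A)
    })
}

records_matrix <- function(records) {
  mids <- unique(vapply(records, `[[`, "", "model_id"))
  if (length(mids) > 1L) stop("records come from different model bases: ",
                              paste(mids, collapse = ", "))
  X <- do.call(rbind, lapply(records, `[[`, "alpha_e"))
  rownames(X) <- vapply(records, function(r)
    paste(r$subject_id, r$au_label, sep = "|"), "")
  X
}

#' Prepare coefficient features for classification
#'
#' Pipeline: per-vector L2 normalization, per-feature standardization with
#' statistics computed on the training records only, then projection onto
#' the variance-ordered principal basis retaining the smallest number of
#' dimensions whose cumulative explained variance reaches `variance`.
#' Test records are transformed with the frozen training statistics.
#'
#' @param train matrix of training feature rows, or list of `au_record`s.
#' @param test optional matrix/list transformed with the training
#'   statistics.
#' @param variance retained cumulative explained-variance fraction
#'   (default 0.95).
#' @return list with `train`, `test` (projected matrices) and `preproc`
#'   (`center`, `scale`, `rotation`, `ncomp`, `variance`).
#' @export
prepare_features <- function(train, test = NULL, variance = 0.95) {
  if (is.list(train) && !is.matrix(train)) train <- records_matrix(train)
  if (!is.null(test) && is.list(test) && !is.matrix(test)) test <- records_matrix(test)
  l2 <- function(X) {
    nrm <- sqrt(rowSums(X * X))
    if (any(nrm == 0)) stop("cannot L2-normalize a zero coefficient vector")
    X / nrm
  }
  Xtr <- l2(train)
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2L, stats::sd)
  scl[scl == 0] <- 1
  std <- function(X) sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Ztr <- std(Xtr)
  sv <- svd(Ztr, nv = min(dim(Ztr)))
  ev <- sv$d^2
  if (sum(ev) == 0) {
    ncomp <- 1L
  } else {
    ncomp <- which(cumsum(ev) / sum(ev) >= variance)[1L]
  }
  rot <- sv$v[, seq_len(ncomp), drop = FALSE]
  preproc <- list(center = ctr, scale = scl, rotation = rot, ncomp = ncomp,
                  variance = variance)
  out_test <- NULL
  if (!is.null(test)) out_test <- std(l2(test)) %*% rot
  list(train = Ztr %*% rot, test = out_test, preproc = preproc)
}

#' Early fusion of two feature sets by concatenation
#'
#' @param a,b feature matrices for the same records in the same order
#'   (checked via rownames when present).
#' @return column-concatenated matrix.
#' @export
fuse_features <- function(a, b) {
  if (is.null(b) || NCOL(b) == 0L) return(a)
  if (is.null(a) || NCOL(a) == 0L) return(b)
  if (nrow(a) != nrow(b)) stop("feature sets cover different record counts")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("feature sets are not aligned on the same records")
  }
  cbind(a, b)
}

rbf_sigma_heuristic <- function(X) {
  d <- stats::dist(X)
  s <- stats::median(d[d > 0])
  if (!is.finite(s) || s <= 0) 1 else s
}

#' Train a One-vs-Rest RBF-SVM over AU coefficients
#'
#' One C-SVC binary classifier per class with the Gaussian RBF kernel
#' `K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`; prediction is the argmax
#' of the per-class decision values (ties towards the lowest class index).
#'
#' @param features n x d numeric matrix.
#' @param labels length-n class labels.
#' @param C regularization constant (default 1).
#' @param sigma kernel bandwidth; default is the median pairwise training
#'   distance.
#' @param preproc optional preprocessing description stored in the bundle.
#' @param model_id identifier of the coefficient basis.
#' @return object of class `au_classifier` with per-class SVMs, `classes`,
#'   `sigma`, `C`.
#' @export
train_au_classifier <- function(features, labels, C = 1, sigma = NULL,
                                preproc = NULL, model_id = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training needs at least 2 classes")
  if (is.null(sigma)) sigma <- rbf_sigma_heuristic(features)
  gamma <- 1 / (2 * sigma^2)
  svms <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(features, y, scale = FALSE, kernel = "radial",
                    gamma = gamma, cost = C)
    dv <- attr(stats::predict(m, features, decision.values = TRUE),
               "decision.values")
    flip <- identical(colnames(dv)[1L], "neg/pos")
    list(svm = m, flip = flip)
  })
  names(svms) <- classes
  structure(list(svms = svms, classes = classes, sigma = sigma, C = C,
                 gamma = gamma, preproc = preproc, model_id = model_id),
            class = "au_classifier")
}

#' Per-class decision values and predictions
#'
#' @param object an `au_classifier`.
#' @param newdata feature matrix on the classifier's input space.
#' @param ... unused.
#' @return list with `class` (predicted labels) and `decision` (n x C
#'   matrix of One-vs-Rest decision values, columns in class order).
#' @export
predict.au_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  dec <- vapply(object$classes, function(cl) {
    ent <- object$svms[[cl]]
    dv <- attr(stats::predict(ent$svm, newdata, decision.values = TRUE),
               "decision.values")[, 1L]
    if (ent$flip) -dv else dv
  }, numeric(nrow(newdata)))
  dec <- matrix(dec, nrow = nrow(newdata),
                dimnames = list(rownames(newdata), object$classes))
  pred <- object$classes[max.col(dec, ties.method = "first")]
  list(class = pred, decision = dec)
}

#' Leave-one-subject-out evaluation of AU detection
#'
#' Each subject's records form the test fold once while all remaining
#' subjects train the preprocessing (statistics frozen per fold) and the
#' One-vs-Rest classifier.  Accumulates a confusion matrix (rows = actual
#' class), per-class F1 and One-vs-Rest ROC-AUC from the pooled decision
#' values, and overall accuracy.
#'
#' @param records list of `au_record`s (one labelled coefficient vector
#'   each) spanning at least 2 subjects.
#' @param opts list: `C`, `sigma`, `variance` (see
#'   [train_au_classifier()], [prepare_features()]).
#' @return object of class `au_evaluation`: `confusion`, `per_class`
#'   (data.frame with F1 and AUC), `accuracy`, `macro_f1`, `folds`
#'   (per-fold detail including the frozen preprocessing statistics).
#' @export
loocv_evaluate <- function(records, opts = list()) {
  subjects <- vapply(records, `[[`, "", "subject_id")
  labels <- vapply(records, `[[`, "", "au_label")
  classes <- sort(unique(labels))
  uniq <- unique(subjects)
  if (length(uniq) < 2L) stop("LOOCV needs at least 2 subjects")
  only_one <- classes[vapply(classes, function(cl)
    length(unique(subjects[labels == cl])) == 1L, TRUE)]
  if (length(only_one)) {
    warning("class(es) present in a single subject only: ",
            paste(only_one, collapse = ", "),
            " (their test fold has no training positives)")
  }
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(actual = classes, predicted = classes))
  all_dec <- NULL; all_actual <- character(0)
  folds <- list()
  for (subj in uniq) {
    te <- which(subjects == subj)
    tr <- which(subjects != subj)
    feats <- prepare_features(records[tr], records[te],
                              variance = opts$variance %||% 0.95)
    clf <- train_au_classifier(feats$train, labels[tr],
                               C = opts$C %||% 1, sigma = opts$sigma,
                               preproc = feats$preproc)
    pr <- predict(clf, feats$test)
    for (i in seq_along(te)) {
      if (labels[te[i]] %in% classes && pr$class[i] %in% classes) {
        confusion[labels[te[i]], pr$class[i]] <-
          confusion[labels[te[i]], pr$class[i]] + 1L
      }
    }
    dec_full <- matrix(-1e6, length(te), length(classes),
                       dimnames = list(NULL, classes))
    dec_full[, colnames(pr$decision)] <- pr$decision
    all_dec <- rbind(all_dec, dec_full)
    all_actual <- c(all_actual, labels[te])
    folds[[subj]] <- list(subject = subj, actual = labels[te],
                          predicted = pr$class, decision = pr$decision,
                          preproc = feats$preproc)
  }
  tp <- diag(confusion)
  prec <- tp / pmax(colSums(confusion), 1L)
  rec <- tp / pmax(rowSums(confusion), 1L)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  auc <- vapply(classes, function(cl) {
    resp <- factor(all_actual == cl, levels = c(FALSE, TRUE))
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::roc(resp, all_dec[, cl], quiet = TRUE,
                         direction = "<", levels = c(FALSE, TRUE))$auc)
  }, numeric(1))
  structure(
    list(confusion = confusion,
         per_class = data.frame(class = classes, f1 = f1, auc = auc,
                                row.names = NULL),
         accuracy = sum(tp) / sum(confusion),
         macro_f1 = mean(f1),
         folds = folds),
    class = "au_evaluation"
  )
}

#' @export
print.au_evaluation <- function(x, ...) {
  cat(sprintf("LOOCV over %d subjects, %d classes: accuracy %.3f, macro F1 %.3f\n",
              length(x$folds), nrow(x$per_class), x$accuracy, x$macro_f1))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Per-AU prototype coefficients
#'
#' Arithmetic mean of the extracted `alpha_e` vectors of all records
#' carrying the AU label.
#'
#' @param records list of `au_record`s.
#' @param au_label the AU to average.
#' @return length-k prototype coefficient vector.
#' @export
compute_au_prototype <- function(records, au_label) {
  sel <- Filter(function(r) identical(r$au_label, au_label), records)
  if (!length(sel)) stop("no records with AU label '", au_label, "'")
  colMeans(do.call(rbind, lapply(sel, `[[`, "alpha_e")))
}

#' Synthesize AU activation on a registered face
#'
#' Applies one or more AU prototype coefficient vectors to a base shape on
#' the model topology (the average face, a fitted neutral, or any
#' registered shape).  Multiple prototypes are combined by element-wise
#' averaging before deformation, so combined AUs need no further
#' processing.
#'
#' @param base [registered_shape()] on the model topology.
#' @param model an `slc_model`.
#' @param prototypes a single prototype vector or list of them.
#' @param combine combination rule for multiple prototypes (only
#'   `"mean"`).
#' @param faces optional template faces attached to the output mesh.
#' @return a [trimesh()] of the deformed face.
#' @export
synthesize_au <- function(base, model, prototypes, combine = "mean",
                          faces = NULL) {
  combine <- match.arg(combine, "mean")
  if (!inherits(base, "registered_shape")) stop("'base' must be a registered_shape")
  if (!identical(base$topology_id, model$topology_id)) {
    stop("base topology '", base$topology_id,
         "' does not match model topology '", model$topology_id, "'")
  }
  if (!is.list(prototypes)) prototypes <- list(prototypes)
  proto <- colMeans(do.call(rbind, prototypes))
  out <- apply_deformation(base, model$components, proto)
  delinearize(out, faces = faces)
}

#' Run the two-step extraction over a whole corpus
#'
#' For each subject of a [generate_corpus()] result: fits the identity to
#' the neutral scan, resamples the fitted neutral onto the scan surface,
#' and extracts AU coefficients from every expressive scan.  Optionally
#' also runs the neutral scan through the expressive step as a
#' null-deformation control (records labelled `"neutral"`).
#'
#' @param model an `slc_model`.
#' @param corpus a [generate_corpus()] result (or any list of subjects
#'   with `neutral_scan` and `scans` entries).
#' @param opts fitting options, see [fit_model()].
#' @param neutral_control also extract neutral-vs-neutral records.
#' @return list of `au_record`s.
#' @export
extract_corpus_records <- function(model, corpus, opts = list(),
                                   neutral_control = FALSE) {
  if (is.null(opts$nose_vertex) && !is.null(corpus$template)) {
    lv <- corpus$template$landmark_vertex
    nm <- rownames(corpus$template$mesh$landmarks)
    opts$nose_vertex <- lv[match("nose_tip", nm)]
  }
  records <- list()
  for (sub in corpus$subjects) {
    idfit <- fit_identity(model, sub$neutral_scan, opts = opts)
    # resample in the model frame: the fitted neutral and the aligned scan
    # surface live in the same coordinates there
    aligned <- aligned_target_mesh(idfit$fit, sub$neutral_scan)
    s_hat <- resample_neutral(idfit$s_n, aligned)
    for (sc in sub$scans) {
      records[[length(records) + 1L]] <-
        extract_au_coefficients(model, s_hat, sc$scan, opts = opts)
    }
    if (neutral_control) {
      records[[length(records) + 1L]] <-
        extract_au_coefficients(model, s_hat, sub$neutral_scan, opts = opts)
    }
  }
  records
}

#' Target scan mapped into the model frame of a fit
#'
#' Applies the composed scan-to-model similarity accumulated during
#' [fit_model()] to the scan's vertices and landmarks.
#'
#' @param fit a `fit_result`.
#' @param scan the [trimesh()] that was fitted.
#' @return a [trimesh()] in the model frame.
#' @export
aligned_target_mesh <- function(fit, scan) {
  tt <- fit$target_transform
  lm <- scan$landmarks
  if (!is.null(lm)) {
    lm2 <- sweep(lm %*% tt$P, 2L, tt$T, "+")
    rownames(lm2) <- rownames(lm)
    lm <- lm2
  }
  trimesh(fit$target_aligned, landmarks = lm,
          subject_id = scan$subject_id, label = scan$label)
}
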