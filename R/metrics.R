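#' Silhouette width of one point against emotion clusters
#'
#' `a` is the mean Euclidean distance from the point to all members of its
#' own-emotion training cluster; `b` is the smallest mean distance to any
#' other emotion's cluster; the width is `(b - a) / max(a, b)` (defined as 0
#' when `max(a, b) = 0`).  Values near 1 mean the point sits well inside its
#' own emotion's cluster, values near -1 that it sits in someone else's.
#'
#' @param coords Numeric coordinate vector of the point (PB activity scale).
#' @param emotion The point's emotion label.
#' @param clusters Named list mapping emotion label to a matrix of member
#'   coordinates (one row per member).
#' @return A number in \[-1, 1\].
#' @export
silhouette_width <- function(coords, emotion, clusters) {
  key <- as.character(emotion)
  own <- clusters[[key]]
  if (is.null(own) || nrow(own) == 0)
    stop("empty own-emotion cluster for emotion ", emotion, call. = FALSE)
  others <- clusters[setdiff(names(clusters), key)]
  others <- others[vapply(others, function(m) nrow(m) > 0, logical(1))]
  stop_if_not(length(others) >= 1, "need at least one other nonempty cluster")
  mean_dist <- function(m)
    mean(sqrt(colSums((t(m) - as.numeric(coords))^2)))
  a <- mean_dist(own)
  b <- min(vapply(others, mean_dist, numeric(1)))
  if (max(a, b) == 0) return(0)
  (b - a) / max(a, b)
}

#' Emotion recognition index (average silhouette width in PB space)
#'
#' The mean silhouette width of the test-sequence PB activities, scored
#' against clusters formed by the training-sequence PB activities grouped by
#' true emotion label.  High values mean test sequences were recognized:
#' their PBs landed inside the self-organized cluster of their own emotion.
#' With `include_train = TRUE` the training points are also scored (each
#' against the clusters excluding itself) and enter the average.
#'
#' @param test_pbs Matrix of test PB activities (rows are sequences).
#' @param test_emotions Integer emotion labels of the test rows.
#' @param train_pbs Matrix of training PB activities.
#' @param train_emotions Integer emotion labels of the training rows.
#' @param include_train Also score training points (default `FALSE`).
#' @return The average silhouette width, in \[-1, 1\].
#' @export
emotion_recognition_index <- function(test_pbs, test_emotions,
                                      train_pbs, train_emotions,
                                      include_train = FALSE) {
  test_pbs <- as.matrix(test_pbs); train_pbs <- as.matrix(train_pbs)
  stop_if_not(nrow(test_pbs) == length(test_emotions) &&
                nrow(train_pbs) == length(train_emotions),
              "labels must match rows")
  if (!all(unique(test_emotions) %in% unique(train_emotions)))
    stop("every test emotion needs a training cluster", call. = FALSE)
  clusters <- lapply(split(seq_along(train_emotions), train_emotions),
                     function(i) train_pbs[i, , drop = FALSE])
  s_test <- vapply(seq_len(nrow(test_pbs)), function(i)
    silhouette_width(test_pbs[i, ], test_emotions[i], clusters), numeric(1))
  if (!include_train) return(mean(s_test))
  s_train <- vapply(seq_len(nrow(train_pbs)), function(i) {
    cl <- lapply(split(setdiff(seq_along(train_emotions), i),
                       train_emotions[setdiff(seq_along(train_emotions), i)]),
                 function(j) train_pbs[j, , drop = FALSE])
    silhouette_width(train_pbs[i, ], train_emotions[i], cl)
  }, numeric(1))
  mean(c(s_test, s_train))
}

#' Extract the PB space of a cross-validated fit
#'
#' @param cv An `"sctrnnpb_cv"` object.
#' @return A data.frame with PB coordinates (`pb_1`, ...), `emotion`,
#'   `role` (`"train"`/`"test"`) and `fold`, suitable for CSV export and
#'   plotting.
#' @export
pb_space <- function(cv) {
  rows <- lapply(seq_along(cv$folds), function(f) {
    fd <- cv$folds[[f]]
    both <- rbind(fd$train_pbs, fd$test_pbs)
    colnames(both) <- paste0("pb_", seq_len(ncol(both)))
    cbind(as.data.frame(both),
          data.frame(emotion = c(fd$train_emotions, fd$test_emotions),
                     role = rep(c("train", "test"),
                                c(nrow(fd$train_pbs), nrow(fd$test_pbs))),
                     fold = f))
  })
  do.call(rbind, rows)
}

#' Scatter plot of a two-dimensional PB space
#'
#' Training points are drawn as filled circles and test points as crosses,
#' colored by emotion.
#'
#' @param space A data.frame from [pb_space()] (or with the same columns).
#' @param ... Passed to [plot()].
#' @return The input, invisibly.
#' @export
plot_pb_space <- function(space, ...) {
  emo <- factor(space$emotion)
  cols <- hcl.colors(nlevels(emo), "Dark 3")[emo]
  pch <- ifelse(space$role == "train", 19, 4)
  plot(space$pb_1, space$pb_2, col = cols, pch = pch,
       xlab = "PB 1 activity", ylab = "PB 2 activity",
       xlim = c(-1, 1), ylim = c(-1, 1), ...)
  legend("topright", legend = levels(emo), col = hcl.colors(nlevels(emo),
         "Dark 3"), pch = 19, title = "emotion", cex = 0.8)
  invisible(space)
}
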