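# Windowing of labeled recordings into fixed-shape training examples.

#' Windowing geometry
#'
#' Defines how a recording is cut into examples. Each example spans
#' `sub_len * n_sub` consecutive samples, divided into `n_sub` sub-windows
#' of `sub_len` samples; each sub-window is reshaped row-major into a
#' `map_rows x map_cols` spatial map per axis (the three axes become
#' channels), which is what the convolutional front end consumes. The
#' default 25-sample sub-window reshaped to 5x5 is the geometry a valid
#' 4x4 convolution producing a 2x2 feature map requires.
#'
#' @param sub_len Samples per sub-window; must equal
#'   `map_rows * map_cols`.
#' @param n_sub Sub-windows per example (temporal depth seen by the LSTM).
#' @param stride Samples between consecutive example end points.
#' @param map_rows,map_cols Spatial shape of one sub-window map.
#' @return Object of class `"windowing_spec"`.
#' @export
windowing_spec <- function(sub_len = 25, n_sub = 8, stride = 5,
                           map_rows = 5, map_cols = 5) {
  if (sub_len != map_rows * map_cols) {
    stop("`sub_len` must equal `map_rows * map_cols` (",
         map_rows, " x ", map_cols, " = ", map_rows * map_cols, ")")
  }
  if (n_sub < 1 || stride < 1) stop("`n_sub` and `stride` must be >= 1")
  structure(
    list(sub_len = as.integer(sub_len), n_sub = as.integer(n_sub),
         stride = as.integer(stride), map_rows = as.integer(map_rows),
         map_cols = as.integer(map_cols)),
    class = "windowing_spec"
  )
}

#' Cut a recording into fixed-shape labeled examples
#'
#' Slides a window of `sub_len * n_sub` samples over the recording with
#' the given stride and emits one example per placement. Each example
#' carries the flattened raw vector `x` of its full span -- `ax` samples
#' first, then `ay`, then `az`, time-ascending within each axis -- and is
#' labeled by the phase of its *final* sample (causal labeling: the label
#' a real-time controller would need at that instant).
#'
#' @param rec An `"accel_recording"`.
#' @param spec A [windowing_spec()].
#' @return Object of class `"gait_examples"`: list with `x` (matrix,
#'   one row per example, `3 * sub_len * n_sub` columns), `y` (integer
#'   phase codes), `subject` (character), `speed`, and the `spec`. A
#'   recording shorter than one span yields zero examples with a warning.
#' @export
build_examples <- function(rec, spec = windowing_spec()) {
  stopifnot(inherits(rec, "accel_recording"), inherits(spec, "windowing_spec"))
  T <- length(rec$ax)
  span <- spec$sub_len * spec$n_sub
  if (T < span) {
    warning("recording of length ", T, " is shorter than one example span (",
            span, "); returning zero examples")
    return(structure(
      list(x = matrix(numeric(0), nrow = 0, ncol = 3 * span),
           y = integer(0), subject = character(0), speed = rec$speed,
           spec = spec),
      class = "gait_examples"
    ))
  }
  n_ex <- (T - span) %/% spec$stride + 1L
  ends <- span + (seq_len(n_ex) - 1L) * spec$stride
  # row i of x = c(ax[start:end], ay[start:end], az[start:end])
  offs <- seq_len(span) - span  # relative indices, end-anchored
  idx <- outer(ends, offs, "+")  # n_ex x span sample indices
  x <- cbind(matrix(rec$ax[idx], n_ex, span),
             matrix(rec$ay[idx], n_ex, span),
             matrix(rec$az[idx], n_ex, span))
  structure(
    list(x = x,
         y = rec$labels[ends],
         subject = rep(as.character(rec$subject_id), n_ex),
         speed = rec$speed,
         spec = spec),
    class = "gait_examples"
  )
}

#' Combine example sets
#'
#' Concatenates several `"gait_examples"` objects (e.g., one per
#' recording of a cohort) into one. All must share the same windowing
#' spec.
#'
#' @param ... `"gait_examples"` objects, or a single list of them.
#' @return A combined `"gait_examples"` object.
#' @export
bind_examples <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "gait_examples")) {
    parts <- parts[[1]]
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "gait_examples")))
  spec <- parts[[1]]$spec
  for (p in parts) {
    if (!identical(unclass(p$spec), unclass(spec))) {
      stop("cannot bind examples with differing windowing specs")
    }
  }
  structure(
    list(x = do.call(rbind, lapply(parts, `[[`, "x")),
         y = do.call(c, lapply(parts, `[[`, "y")),
         subject = do.call(c, lapply(parts, `[[`, "subject")),
         speed = parts[[1]]$speed,
         spec = spec),
    class = "gait_examples"
  )
}

#' @export
print.gait_examples <- function(x, ...) {
  cat("Gait examples:", nrow(x$x), "examples x", ncol(x$x),
      "raw features (", x$spec$n_sub, "sub-windows of", x$spec$sub_len,
      "samples )\n")
  if (nrow(x$x) > 0) {
    prop <- table(factor(x$y, levels = 0:3, labels = phase_levels()))
    cat("  label proportions:",
        paste(sprintf("%s=%.3f", names(prop), prop / length(x$y)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
`[.gait_examples` <- function(x, i) {
  structure(
    list(x = x$x[i, , drop = FALSE], y = x$y[i], subject = x$subject[i],
         speed = x$speed, spec = x$spec),
    class = "gait_examples"
  )
}

#' @export
length.gait_examples <- function(x) nrow(x$x)

#' Spatial maps of one example
#'
#' Reassembles the raw flattened vector of example `i` into the stack of
#' sub-window maps the convolutional front end sees: an array of shape
#' `map_rows x map_cols x 3 x n_sub` (axes as channels). Each
#' `sub_len`-sample block fills its map row-major.
#'
#' @param examples A `"gait_examples"` object.
#' @param i Example index.
#' @return A 4-d numeric array.
#' @export
example_maps <- function(examples, i) {
  stopifnot(inherits(examples, "gait_examples"))
  sp <- examples$spec
  span <- sp$sub_len * sp$n_sub
  x <- examples$x[i, ]
  out <- array(0, dim = c(sp$map_rows, sp$map_cols, 3L, sp$n_sub))
  for (s in seq_len(sp$n_sub)) {
    for (axis in 1:3) {
      block <- x[(axis - 1L) * span + (s - 1L) * sp$sub_len +
                   seq_len(sp$sub_len)]
      # row-major fill: t(matrix(..)) turns R's column-major into row-major
      out[, , axis, s] <- t(matrix(block, sp$map_cols, sp$map_rows))
    }
  }
  out
}

#' Split examples into training and test sets
#'
#' Reproduces a 70/30 holdout: `round(fraction * N)` examples train, the
#' rest test, drawn deterministically from `seed`. `mode = "window"`
#' samples windows at random (the protocol emulated by default);
#' `mode = "subject"` keeps every example of a subject on one side, which
#' avoids subject-identity leakage between the sets, and fills the
#' training side subject by subject until it holds at least
#' `fraction * N` examples.
#'
#' @param examples A `"gait_examples"` object with >= 2 examples.
#' @param fraction Training fraction in (0, 1); default 0.70.
#' @param seed Integer seed controlling the draw.
#' @param mode `"window"` or `"subject"`.
#' @return List with `"gait_examples"` elements `train` and `test`.
#' @export
split_train_test <- function(examples, fraction = 0.7, seed = 1L,
                             mode = c("window", "subject")) {
  stopifnot(inherits(examples, "gait_examples"))
  mode <- match.arg(mode)
  N <- nrow(examples$x)
  if (N < 2) stop("need at least 2 examples to split")
  if (!(fraction > 0 && fraction < 1)) stop("`fraction` must be in (0, 1)")
  if (mode == "window") {
    idx <- with_seed(seed, sample.int(N, size = round(fraction * N)))
  } else {
    subj <- unique(examples$subject)
    if (length(subj) < 2) {
      stop("subject-mode split requires at least 2 subjects")
    }
    ord <- with_seed(seed, sample(subj))
    counts <- vapply(ord, function(s) sum(examples$subject == s), integer(1))
    take <- ord[seq_len(which(cumsum(counts) >= fraction * N)[1])]
    if (length(take) == length(subj)) take <- take[-length(take)]
    idx <- which(examples$subject %in% take)
  }
  list(train = examples[sort(idx)], test = examples[sort(setdiff(seq_len(N), idx))])
}
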