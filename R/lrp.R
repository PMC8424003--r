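#' Configuration for layer-wise relevance propagation (epsilon rule)
#'
#' @param epsilon non-negative stabilizer of the epsilon rule. The default 1
#'   keeps only the strongest contributions, absorbing noise relevance.
#' @param start where the initial relevance is taken: the winning class's
#'   softmax output (default) or its pre-softmax logit.
#' @param sign_stabilized add `epsilon * sign(z)` (default) rather than a bare
#'   `+ epsilon`, avoiding cancellation for negative pre-activations; set
#'   `FALSE` for the literal bare-epsilon denominator.
#' @param absolute collapse side traces on absolute relevance values instead
#'   of signed ones.
#' @return list of class `lrp_config`.
#' @export
lrp_config <- function(epsilon = 1.0, start = c("softmax_output", "logit"),
                       sign_stabilized = TRUE, absolute = FALSE) {
  assert_that(is.numeric(epsilon) && epsilon >= 0, "epsilon must be >= 0")
  structure(list(epsilon = epsilon, start = match.arg(start),
                 sign_stabilized = isTRUE(sign_stabilized),
                 absolute = isTRUE(absolute)),
            class = "lrp_config")
}

# stabilized denominator of the epsilon rule
lrp_denom <- function(z, epsilon, sign_stabilized) {
  if (sign_stabilized) {
    s <- sign(z)
    s[s == 0] <- 1
    d <- z + epsilon * s
  } else {
    d <- z + epsilon
  }
  d[d == 0] <- .Machine$double.eps
  d
}

# epsilon-rule redistribution through one dense linear map:
# a: input activations (length K), W: K x n weights, b: length-n bias,
# r_out: length-n relevance. Returns length-K input relevance; the bias
# term takes part in the denominator but its relevance share is absorbed.
lrp_linear <- function(a, W, b, r_out, epsilon = 0,
                       sign_stabilized = TRUE) {
  z <- as.numeric(crossprod(W, a)) + b
  f <- r_out / lrp_denom(z, epsilon, sign_stabilized)
  a * as.numeric(W %*% f)
}

#' Layer-wise relevance propagation through a trained ECM network
#'
#' Starts from the winning class's score and redistributes it backwards:
#' convolution and fully-connected layers follow the epsilon rule (the
#' relevance flowing to input k is proportional to `a_k * w_{n,k}` over the
#' stabilized pre-activation, bias included in the denominator);
#' batch-normalization affine transforms are folded into the adjacent
#' convolution before redistribution; ReLU passes relevance unchanged;
#' max-pooling routes each output's relevance to its argmax input
#' (winner-take-all).
#'
#' @param model trained `ecm_cnn`.
#' @param pixels 10 x 219 ECM-image matrix.
#' @param cfg an [lrp_config()].
#' @return object of class `relevance_map`: list with `scores` (10 x 219
#'   signed relevance matrix), `R_top` (initial relevance), `winner` (class
#'   the relevance explains) and `layer_sums` (audit trail of total relevance
#'   after each propagation step).
#' @export
lrp_epsilon <- function(model, pixels, cfg = lrp_config()) {
  assert_that(inherits(model, "ecm_cnn"), "model must be an ecm_cnn")
  x <- as_batch_array(pixels)
  fwd <- net_forward(model, x, mode = "infer", keep_cache = TRUE)
  p <- fwd$probs[, 1]
  win <- which.max(p)
  logits <- fwd$caches[[length(model$layers)]]$z[, 1]
  r_top <- if (cfg$start == "softmax_output") p[win] else logits[win]

  nl <- length(model$layers)
  r <- numeric(2)
  r[win] <- r_top
  sums <- tibble::tibble(layer = integer(), type = character(), total = numeric())
  pending_bn <- NULL
  for (i in rev(seq_len(nl))) {
    l <- model$layers[[i]]
    if (l$type == "softmax") next
    if (l$type == "bn") {
      pending_bn <- l
      next
    }
    if (l$type == "relu") {
      # relevance passes unchanged
    } else if (l$type == "pool") {
      pb <- pool_backward(l, r, fwd$caches[[i]])
      r <- pb$dx
    } else if (l$type == "fc") {
      a <- fwd$caches[[i]]$xm[, 1]
      rk <- lrp_linear(a, t(l$W), l$b, as.numeric(r), cfg$epsilon,
                       cfg$sign_stabilized)
      r <- array(rk, fwd$caches[[i]]$in_dim)
    } else if (l$type == "conv") {
      W <- l$W
      b <- l$b
      if (!is.null(pending_bn)) {
        sc <- pending_bn$gamma / sqrt(pending_bn$running_var + 1e-5)
        W <- sweep(W, 2L, sc, `*`)
        b <- (b - pending_bn$running_mean) * sc + pending_bn$beta
        pending_bn <- NULL
      }
      g <- l$geom
      cols <- fwd$caches[[i]]$cols
      z <- cols %*% W
      z <- z + rep(b, each = nrow(z))
      r_out <- array_to_cols(r, g, 1L, ncol(W))
      f <- r_out / lrp_denom(z, cfg$epsilon, cfg$sign_stabilized)
      rcols <- cols * tcrossprod(f, W)
      r <- col2im(rcols, g, 1L)
    }
    sums <- dplyr::bind_rows(sums, tibble::tibble(
      layer = i, type = l$type, total = sum(r)))
  }
  scores <- matrix(r, 10L, 219L)
  structure(list(scores = scores, R_top = r_top,
                 winner = model$classes[win], probs = p,
                 layer_sums = sums, config = cfg),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf(
    "<relevance_map> explaining %s (R_top = %.4f, epsilon = %g): input sum %.4f\n",
    x$winner, x$R_top, x$config$epsilon, sum(x$scores)))
  invisible(x)
}

#' Collapse a relevance map into leftside/rightside time-domain traces
#'
#' The left section (columns 1-63, 125 Hz) is already beat-aligned across the
#' ten rows — the R peak sits at the section boundary — so the leftside trace
#' is the plain column-wise mean over rows, on the beat-relative time axis
#' `[-0.5, 0)` s. Each right-section pixel (columns 64-219, one per 8-sample
#' span at 500 Hz) is remapped through the downsample map and its row's beat
#' time to the record time axis; contributions falling on the same record
#' sample are averaged (coverage-weighted), giving the rightside trace over
#' the window's segment.
#'
#' @param rmap a `relevance_map`.
#' @param window the window row (from the `ecm_dataset` metadata) the image
#'   was built from.
#' @param dmap the [downsample_map()].
#' @param absolute average absolute relevance instead of signed.
#' @return list of class `side_traces`: `leftside` tibble (63 rows:
#'   `time_s`, `relevance`), `rightside` tibble (`sample`, `time_s`,
#'   `relevance`, `coverage`).
#' @export
collapse_sides <- function(rmap, window, dmap = downsample_map(),
                           absolute = rmap$config$absolute %||% FALSE) {
  scores <- rmap$scores
  if (absolute) scores <- abs(scores)
  b <- window$beat_indices[[1]]
  assert_that(length(b) == 10L, "window must carry 10 beats")
  s0 <- window$segment_start[[1]]
  s1 <- window$segment_end[[1]]
  left <- tibble::tibble(
    time_s = (dmap$left_source_indices - 250) / dmap$fs,
    relevance = colMeans(scores[, 1:63, drop = FALSE])
  )
  seg_len <- s1 - s0
  acc <- numeric(seg_len)
  cov <- numeric(seg_len)
  for (i in 1:10) {
    starts <- b[i] - 250L + dmap$right_source_indices - s0   # 0-based in segment
    for (j in seq_along(starts)) {
      lo <- starts[j]
      hi <- min(lo + dmap$right_factor, seg_len)
      if (hi <= 0 || lo >= seg_len) next
      lo <- max(lo, 0L)
      idx <- (lo + 1L):hi
      acc[idx] <- acc[idx] + scores[i, 63L + j]
      cov[idx] <- cov[idx] + 1
    }
  }
  right <- tibble::tibble(
    sample = s0 + seq_len(seg_len) - 1L,
    time_s = (s0 + seq_len(seg_len) - 1L) / dmap$fs,
    relevance = ifelse(cov > 0, acc / pmax(cov, 1), NA_real_),
    coverage = as.integer(cov)
  )
  structure(list(leftside = left, rightside = right),
            class = "side_traces")
}

#' Four-panel LRP figure
#'
#' Standard presentation of an explained decision: the ECM-image, the
#' relevance heatmap (symmetric diverging scale centered at zero),
#' the rightside record-time trace, and the leftside beat-relative trace.
#'
#' @param pixels the 10 x 219 ECM-image.
#' @param rmap its `relevance_map`.
#' @param traces the [collapse_sides()] output.
#' @return a patchwork-free list-less ggplot built with facets; use
#'   [render_lrp()] to write it to a PNG file.
#' @export
plot_lrp <- function(pixels, rmap, traces) {
  img <- tidyr::expand_grid(row = 1:10, col = 1:219)
  img$value <- as.vector(t(pixels))
  img$panel <- "1: ECM-image (mV)"
  rel <- tidyr::expand_grid(row = 1:10, col = 1:219)
  rel$value <- as.vector(t(rmap$scores))
  rel$panel <- "2: LRP relevance"
  heat <- dplyr::bind_rows(img, rel)
  lim <- max(abs(rel$value))
  p_heat <- ggplot2::ggplot(heat, ggplot2::aes(.data$col, .data$row,
                                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = NULL) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free") +
    ggplot2::theme_minimal()
  tr <- dplyr::bind_rows(
    dplyr::mutate(traces$rightside[, c("time_s", "relevance")],
                  panel = "3: rightside-LRP (record time, s)"),
    dplyr::mutate(traces$leftside, panel = "4: leftside-LRP (beat-relative, s)")
  )
  p_tr <- ggplot2::ggplot(tr, ggplot2::aes(.data$time_s, .data$relevance)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "relevance")
  list(heatmaps = p_heat, traces = p_tr)
}

#' Write the four-panel LRP figure to PNG files
#'
#' @param pixels,rmap,traces as for [plot_lrp()].
#' @param out_path base output path; `_maps.png` and `_traces.png` suffixes
#'   are appended.
#' @return invisibly, the paths written.
#' @export
render_lrp <- function(pixels, rmap, traces, out_path) {
  ps <- plot_lrp(pixels, rmap, traces)
  paths <- paste0(sub("\\.png$", "", out_path), c("_maps.png", "_traces.png"))
  ggplot2::ggsave(paths[1], ps$heatmaps, width = 8, height = 5, dpi = 120)
  ggplot2::ggsave(paths[2], ps$traces, width = 8, height = 5, dpi = 120)
  invisible(paths)
}
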