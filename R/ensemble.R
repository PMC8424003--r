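#' Train the three-split majority-of-votes ensemble
#'
#' Performs three seeded patient-wise 80/20 splits of the cohort (validation
#' patients never contribute training images), and for each split balances
#' the classes and trains one network, yielding the Net 1 / Net 2 / Net 3
#' ensemble whose final decision is the majority of votes.
#'
#' @param records list of preprocessed, beat-annotated [ecg_record()]s at
#'   500 Hz from at least 5 distinct patients.
#' @param cfg a [train_config()].
#' @param hop_beats window hop used to build training images (5 = overlapping
#'   training augmentation).
#' @param channel channel used for ECM construction.
#' @return an `ecm_ensemble`: list with `nets` (3 `ecm_cnn`), `splits`
#'   (per-split patient assignment) and `validation` (per-split metrics
#'   tibble).
#' @export
train_three_splits <- function(records, cfg = train_config(), hop_beats = 5L,
                               channel = 1L) {
  patients <- unique(purrr::map_chr(records, "patient_id"))
  assert_that(length(patients) >= 5L,
              "patient-wise splitting needs at least 5 distinct patients")
  datasets <- purrr::map(records, build_ecm_dataset, channel = channel,
                         hop_beats = hop_beats)
  by_patient <- split(datasets, purrr::map_chr(records, "patient_id"))
  n_val <- max(1L, round(0.2 * length(patients)))
  nets <- vector("list", 3L)
  splits <- vector("list", 3L)
  val_metrics <- vector("list", 3L)
  for (s in 1:3) {
    sseed <- child_seed(cfg$seed, paste0("split", s))
    val_p <- with_seed(sseed, sample(patients, n_val))
    train_p <- setdiff(patients, val_p)
    train_ds <- bind_ecm_datasets(unlist(by_patient[train_p], recursive = FALSE))
    val_ds <- bind_ecm_datasets(unlist(by_patient[val_p], recursive = FALSE))
    net_cfg <- cfg
    net_cfg$seed <- child_seed(sseed, "net")
    net <- build_network(seed = net_cfg$seed)
    net <- train(net, train_ds, net_cfg)
    nets[[s]] <- net
    splits[[s]] <- tibble::tibble(
      split = s,
      patient_id = c(train_p, val_p),
      role = rep(c("train", "validation"), c(length(train_p), length(val_p)))
    )
    vm <- tibble::tibble(split = s, n_val = dim(val_ds$pixels)[3],
                         accuracy = NA_real_)
    if (vm$n_val > 0L) {
      pred <- forward(net, val_ds$pixels)
      vm$accuracy <- mean(pred$label == val_ds$meta$label)
    }
    val_metrics[[s]] <- vm
  }
  structure(list(nets = nets, splits = dplyr::bind_rows(splits),
                 validation = dplyr::bind_rows(val_metrics),
                 hop_beats = hop_beats, channel = channel),
            class = "ecm_ensemble")
}

#' Majority-of-votes classification of ECM-images
#'
#' Each of the three networks casts an argmax vote per image; the ensemble
#' label is the majority. With three voters the majority is always defined.
#'
#' @param ens an `ecm_ensemble` (or plain list of 3 `ecm_cnn`).
#' @param pixels 10 x 219 matrix or 10 x 219 x N array.
#' @return tibble with per-net probabilities (`p_AF_net1..3`), per-net votes
#'   (`vote_net1..3`), and the majority `label`.
#' @export
mov_classify <- function(ens, pixels) {
  nets <- if (inherits(ens, "ecm_ensemble")) ens$nets else ens
  assert_that(length(nets) == 3L, "majority of votes requires exactly 3 networks")
  preds <- purrr::map(nets, forward, pixels = pixels)
  out <- tibble::tibble(.rows = nrow(preds[[1]]))
  for (i in 1:3) {
    out[[paste0("p_AF_net", i)]] <- preds[[i]]$p_AF
    out[[paste0("vote_net", i)]] <- preds[[i]]$label
  }
  votes_af <- (preds[[1]]$label == "AF") + (preds[[2]]$label == "AF") +
    (preds[[3]]$label == "AF")
  out$label <- ifelse(votes_af >= 2L, "AF", "NONAF")
  out
}

#' @export
print.ecm_ensemble <- function(x, ...) {
  cat(sprintf("<ecm_ensemble> 3 nets, mean validation accuracy %.3f\n",
              mean(x$validation$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' Tidy the per-split validation results of an ensemble
#' @param x an `ecm_ensemble`.
#' @param ... unused.
#' @return tibble with one row per split: validation size and accuracy.
#' @export
tidy.ecm_ensemble <- function(x, ...) x$validation

#' One-row summary of an ensemble
#' @param x an `ecm_ensemble`.
#' @param ... unused.
#' @return tibble with parameter count per net and mean/sd validation
#'   accuracy.
#' @export
glance.ecm_ensemble <- function(x, ...) {
  tibble::tibble(
    n_nets = length(x$nets),
    parameters_per_net = count_parameters(x$nets[[1]]),
    mean_val_accuracy = mean(x$validation$accuracy, na.rm = TRUE),
    sd_val_accuracy = sd(x$validation$accuracy, na.rm = TRUE)
  )
}

#' Tidy per-epoch training log of a network
#' @param x an `ecm_cnn`.
#' @param ... unused.
#' @return tibble of per-epoch loss and accuracy.
#' @export
tidy.ecm_cnn <- function(x, ...) {
  x$log %||% tibble::tibble(epoch = integer(), loss = numeric(),
                            accuracy = numeric())
}

#' One-row summary of a network
#' @param x an `ecm_cnn`.
#' @param ... unused.
#' @return tibble with layer/parameter counts and training state.
#' @export
glance.ecm_cnn <- function(x, ...) {
  tibble::tibble(
    n_layers = length(x$layers),
    n_parameters = count_parameters(x),
    trained = x$trained,
    final_train_accuracy = if (!is.null(x$log) && nrow(x$log)) {
      x$log$accuracy[nrow(x$log)]
    } else {
      NA_real_
    }
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy
#' @export
generics::glance
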