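#' Transfer-learning configuration for above/below-limit verdicts
#'
#' A binary 1D CNN is pretrained on DI-water data spiked well below and well
#' above the WHO drinking-water limit for As3+ (0.13 uM): 0.05, 0.5 and 5 nM
#' versus 5, 50 and 500 uM. To adapt to a new water matrix the convolutional
#' weights of layers 3 and 4 are frozen, layers 1-2 and the sigmoid head are
#' fine-tuned on 80 spiked spectra per class with Adam at learning rate
#' 0.001 under binary cross-entropy.
#'
#' @param below_concentrations,above_concentrations Pretraining ladders,
#'   mol/L; every `below` entry must sit under `who_limit` and every
#'   `above` entry over it.
#' @param who_limit Decision threshold, mol/L (default the As3+ WHO limit).
#' @param finetune_n_per_class Spectra per class for fine-tuning.
#' @param learning_rate Adam learning rate for both phases.
#' @param epochs Epoch budget (the regression protocol's 35 with patience
#'   10 is reused).
#' @param patience Early-stopping patience.
#' @param seed Integer seed.
#' @return A list of class `transfer_config`.
#' @export
transfer_config <- function(below_concentrations = c(0.05e-9, 0.5e-9, 5e-9),
                            above_concentrations = c(5e-6, 50e-6, 500e-6),
                            who_limit = mass_to_molar(10e-6, salt_spec("NaAsO2"), "element"),
                            finetune_n_per_class = 80L,
                            learning_rate = 0.001, epochs = 35L, patience = 10L,
                            seed = 1L) {
  if (any(below_concentrations >= who_limit) || any(above_concentrations <= who_limit)) {
    abort("Pretraining classes must straddle `who_limit`.")
  }
  structure(list(below_concentrations = below_concentrations,
                 above_concentrations = above_concentrations,
                 who_limit = who_limit,
                 finetune_n_per_class = as.integer(finetune_n_per_class),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "transfer_config")
}

#' Wastewater preset of the transfer protocol
#'
#' Fine-tuning ladder 1.3 nM and 13 nM (below) plus 1.3 uM and 13 uM
#' (above); tap water uses 1.3 nM, 13 nM and 1.3 uM.
#'
#' @param matrix `"tap"` or `"wastewater"`.
#' @return Named list of fine-tuning concentrations and binary labels.
#' @export
finetune_ladder <- function(matrix = c("tap", "wastewater")) {
  matrix <- match.arg(matrix)
  switch(matrix,
    tap = list(concentrations = c(1.3e-9, 13e-9, 1.3e-6), above = c(0, 0, 1)),
    wastewater = list(concentrations = c(1.3e-9, 13e-9, 1.3e-6, 13e-6),
                      above = c(0, 0, 1, 1))
  )
}

label_above <- function(fm, who_limit) {
  fm$above_who <- as.integer(fm$concentration_molar > who_limit)
  fm
}

#' Pretrain the binary above/below CNN on DI-water features
#'
#' The convolutional body follows the regression architecture; the head is
#' a single sigmoid unit on the flattened features, trained with binary
#' cross-entropy.
#'
#' @param fm_di DI-water `sers_features` with an `above_who` 0/1 column (see
#'   [label_above()]); both classes must be present.
#' @param cfg A [transfer_config()].
#' @param spec A [cnn_spec()] for the convolutional body.
#' @return A trained binary `sers_cnn`.
#' @export
pretrain_binary <- function(fm_di, cfg = transfer_config(), spec = cnn_spec()) {
  if (is.null(fm_di$above_who)) fm_di <- label_above(fm_di, cfg$who_limit)
  if (length(unique(fm_di$above_who)) < 2L) {
    abort("Pretraining needs both binary classes.")
  }
  spec$seed <- derive_seed(cfg$seed, "pretrain")
  spec$learning_rate <- cfg$learning_rate
  model <- build_cnn(spec, head = "binary")
  train_cnn(model, fm_di, target = "above_who", epochs = cfg$epochs,
            patience = cfg$patience, seed = derive_seed(cfg$seed, "pretrain_fit"))
}

#' Fine-tune a pretrained binary CNN on a new water matrix
#'
#' Freezes the third and fourth convolutional layers exactly (their weights
#' are bit-identical before and after) and updates conv layers 1-2, the
#' batch-normalization parameters and the sigmoid head on
#' `finetune_n_per_class` spectra per spiked class. Zero epochs return the
#' model unchanged.
#'
#' @param model A [pretrain_binary()] model.
#' @param fm_new `sers_features` from the new matrix with `above_who`
#'   labels; every class (`class_index`) must have at least
#'   `finetune_n_per_class` rows.
#' @param cfg A [transfer_config()].
#' @param epochs Epoch budget (default `cfg$epochs`).
#' @return The fine-tuned `sers_cnn`.
#' @export
fine_tune <- function(model, fm_new, cfg = transfer_config(), epochs = cfg$epochs) {
  if (!model$trained) abort("`model` must be pretrained before fine-tuning.")
  if (is.null(fm_new$above_who)) fm_new <- label_above(fm_new, cfg$who_limit)
  counts <- table(fm_new$class_index)
  if (any(counts < cfg$finetune_n_per_class)) {
    abort(sprintf("Every fine-tuning class needs >= %d spectra.",
                  cfg$finetune_n_per_class))
  }
  fm_new <- with_seed(derive_seed(cfg$seed, "finetune_sample"), {
    keep <- unlist(lapply(split(seq_len(nrow(fm_new)), fm_new$class_index),
                          function(idx) sample(idx, cfg$finetune_n_per_class)))
    fm_new[sort(keep), ]
  })
  conv_ids <- which(vapply(model$layers, `[[`, "", "type") == "conv1d")
  trainable <- rep(TRUE, length(model$layers))
  trainable[conv_ids[3:4]] <- FALSE
  train_cnn(model, fm_new, target = "above_who", epochs = epochs,
            patience = cfg$patience, trainable = trainable,
            seed = derive_seed(cfg$seed, "finetune_fit"))
}

#' Binary accuracy of an above/below model
#'
#' @param model A binary `sers_cnn`.
#' @param fm Features with `above_who` labels.
#' @return Fraction of spectra called on the correct side of the limit.
#' @export
binary_accuracy <- function(model, fm) {
  mean((predict(model, fm) > 0.5) == (fm$above_who == 1L))
}

#' Verdict for a water sample
#'
#' Every spectrum of the sample is classified at probability threshold 0.5;
#' the verdict is the majority call, with ties resolved to `"above"` as the
#' fail-safe for water safety. The fraction of spectra voting "below" is
#' reported alongside.
#'
#' @param model A binary `sers_cnn`.
#' @param fm `sers_features` of the sample's spectra (>= 1 row).
#' @return List of class `sers_verdict`: `verdict` (`"above"`/`"below"`),
#'   `fraction_below`, `n_spectra` and the WHO limit used.
#' @param who_limit Threshold reported in the verdict, mol/L.
#' @export
classify_water_sample <- function(model, fm, who_limit = transfer_config()$who_limit) {
  if (nrow(fm) == 0L) abort("Need at least one spectrum for a verdict.")
  p <- predict(model, fm)
  below <- p <= 0.5
  frac_below <- mean(below)
  structure(list(
    verdict = if (frac_below > 0.5) "below" else "above",
    fraction_below = frac_below,
    n_spectra = length(p),
    who_limit = who_limit
  ), class = "sers_verdict")
}
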