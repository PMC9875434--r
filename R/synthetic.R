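#' Specification for a synthetic solubility dataset
#'
#' The generator emulates a balanced two-class benchmark of protein
#' sequences whose label correlates with residue composition: the soluble
#' class is enriched in the selected signal channels (charged residues
#' K/R/D/E, turn formers G/N/S) and depleted in hydrophobic residues, and
#' vice versa for the insoluble class.
#'
#' `effect_size` acts on the log scale: residues in a positively
#' (negatively) signed signal group have their sampling log-probability
#' shifted by `+effect_size/10` (`-effect_size/10`) in the soluble class
#' and the opposite in the insoluble class. At `effect_size = 2` this
#' moves the mean charged+turn residue fraction by roughly 0.15 between
#' classes -- a strong, cleanly learnable signal; `effect_size = 0` makes
#' the classes exchangeable.
#'
#' @param n Samples per class (classes are exactly balanced).
#' @param length_range Integer (min, max) sequence lengths; min >= 10.
#' @param effect_size Compositional shift on the log-odds scale (>= 0).
#' @param signal_channels Subset of
#'   `c("charge_fraction", "turn_formers", "hydrophobicity")`.
#' @param noise Label-flip probability in `[0, 0.5)`.
#' @param seed Integer seed; the whole generation is reproducible from it.
#' @param background Length-20 residue sampling weights (default uniform).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n = 100L, length_range = c(50L, 600L),
                       effect_size = 1,
                       signal_channels = c("charge_fraction",
                                           "turn_formers",
                                           "hydrophobicity"),
                       noise = 0, seed = 1L,
                       background = rep(1 / 20, 20L)) {
  signal_channels <- match.arg(signal_channels, several.ok = TRUE)
  stopifnot(n >= 1L, length(length_range) == 2L,
            length_range[1] >= 10L, length_range[1] <= length_range[2],
            effect_size >= 0, noise >= 0, noise < 0.5,
            length(background) == 20L, all(background > 0))
  out <- list(n = as.integer(n),
              length_range = as.integer(length_range),
              effect_size = effect_size,
              signal_channels = signal_channels,
              noise = noise, seed = as.integer(seed),
              background = background / sum(background))
  class(out) <- "synth_spec"
  out
}

# signed signal direction over the 20 residues for the selected channels
signal_direction <- function(channels) {
  s <- setNames(numeric(20L), AA_ALPHABET)
  if ("charge_fraction" %in% channels) s[AA_CHARGED] <- 1
  if ("turn_formers" %in% channels) s[AA_TURN] <- 1
  if ("hydrophobicity" %in% channels) s[AA_HYDROPHOBIC] <- -1
  s
}

#' Generate a labeled synthetic dataset
#'
#' Draws balanced soluble/insoluble sequences from per-class residue
#' distributions tilted along the configured signal channels (see
#' [synth_spec()]), optionally flips labels with probability `noise`, and
#' returns a strict-valid [solu_dataset()].
#'
#' @param spec A [synth_spec()].
#' @return A [solu_dataset()] with `2 * spec$n` records
#'   (`S0001...` soluble, `I0001...` insoluble; ids keep the generating
#'   class even when the label is noise-flipped).
#' @export
generate_dataset <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  s <- signal_direction(spec$signal_channels)
  tilt <- spec$effect_size * s / 10
  p_sol <- spec$background * exp(tilt);  p_sol <- p_sol / sum(p_sol)
  p_ins <- spec$background * exp(-tilt); p_ins <- p_ins / sum(p_ins)
  draw <- function(m, p, prefix) {
    len <- sample(spec$length_range[1]:spec$length_range[2], m, replace = TRUE)
    seqs <- vapply(len, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = p), collapse = ""), "")
    list(id = sprintf("%s%04d", prefix, seq_len(m)), seq = seqs)
  }
  sol <- draw(spec$n, p_sol, "S")
  ins <- draw(spec$n, p_ins, "I")
  label <- c(rep(1L, spec$n), rep(0L, spec$n))
  if (spec$noise > 0) {
    flip <- runif(2L * spec$n) < spec$noise
    label[flip] <- 1L - label[flip]
  }
  solu_dataset(c(sol$id, ins$id), c(sol$seq, ins$seq), label)
}

#' Generate a feature matrix with a planted class signal
#'
#' Direct tabular analogue used to study feature selection: `p` standard
#' normal columns, of which `n_informative` get a between-class mean shift
#' of `effect_size` standard deviations. Ground-truth informative column
#' indices are attached.
#'
#' @param n Total samples (balanced classes).
#' @param p Number of feature columns.
#' @param n_informative Number of signal-carrying columns (placed at
#'   random positions).
#' @param effect_size Class mean difference in SD units.
#' @param seed Integer seed.
#' @return List with `X` (n x p matrix), `y` (0/1), and `informative`
#'   (column indices).
#' @export
generate_feature_matrix <- function(n = 1000L, p = 523L, n_informative = 10L,
                                    effect_size = 2, seed = 1L) {
  stopifnot(n_informative <= p, n >= 2L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  informative <- sort(sample.int(p, n_informative))
  X[, informative] <- X[, informative] +
    outer(ifelse(y == 1L, effect_size / 2, -effect_size / 2),
          rep(1, n_informative))
  colnames(X) <- sprintf("F%03d", seq_len(p))
  list(X = X, y = y, informative = informative)
}
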