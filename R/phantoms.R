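# Two-class synthetic brain phantoms: an elliptical "brain" with a central
# dark "ventricle" and band-limited interior texture. The two class-dependent
# axes mirror what the dual-stream method claims to exploit: the dominant
# texture frequency (visible to the Gabor bank) and the ventricle size
# (structure the locality-preserving traversal turns into slow audio
# envelopes). Nine slices per synthetic subject mimic the per-scan slice
# structure of real studies.

#' Phantom generator configuration
#'
#' `effect_size` interpolates every class-dependent parameter between the
#' class-0 value (`effect_size = 0`: both classes are drawn from the same
#' distribution) and the full class-1 value (`effect_size = 1`).
#'
#' @param image_size Side of the square slice in pixels (default 150, the
#'   image-stream input size, avoiding resizing confounds).
#' @param n_per_class Number of slices per class (subjects of 9 slices each;
#'   the last subject may carry fewer).
#' @param effect_size Separation knob in `[0, 1]`.
#' @param texture_freq Length-2 vector: dominant texture frequency
#'   (cycles/pixel) of class 0 and class 1 at full effect.
#' @param ventricle_ratio Length-2 vector: ventricle radius as a fraction of
#'   the brain radius per class at full effect.
#' @param noise_sd Additive Gaussian pixel noise SD.
#' @param slices_per_subject Slices drawn per synthetic subject (default 9).
#' @param seed RNG seed; generation is bit-reproducible.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 150, n_per_class = 100,
                           effect_size = 1,
                           texture_freq = c(0.07, 0.13),
                           ventricle_ratio = c(0.16, 0.30),
                           noise_sd = 0.04, slices_per_subject = 9,
                           seed = 1) {
  stopifnot(image_size >= 16, n_per_class >= 1,
            effect_size >= 0, effect_size <= 1,
            length(texture_freq) == 2, length(ventricle_ratio) == 2,
            noise_sd >= 0, slices_per_subject >= 1)
  structure(list(image_size = as.integer(image_size),
                 n_per_class = as.integer(n_per_class),
                 effect_size = effect_size,
                 texture_freq = texture_freq,
                 ventricle_ratio = ventricle_ratio,
                 noise_sd = noise_sd,
                 slices_per_subject = as.integer(slices_per_subject),
                 seed = seed),
            class = "phantom_config")
}

# band-limited texture: superposition of random-phase plane waves near f0
phantom_texture <- function(n, f0, n_waves = 8) {
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE)   # x = column
  ys <- matrix(0:(n - 1), n, n)                 # y = row
  tex <- matrix(0, n, n)
  for (i in seq_len(n_waves)) {
    f <- f0 * stats::runif(1, 0.9, 1.1)
    th <- stats::runif(1, 0, pi)
    ph <- stats::runif(1, 0, 2 * pi)
    tex <- tex + cos(2 * pi * f * (xs * cos(th) + ys * sin(th)) + ph)
  }
  tex / n_waves
}

phantom_slice <- function(n, freq, vratio, noise_sd) {
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE)
  ys <- matrix(0:(n - 1), n, n)
  cx <- (n - 1) / 2 * stats::runif(1, 0.97, 1.03)
  cy <- (n - 1) / 2 * stats::runif(1, 0.97, 1.03)
  ax <- 0.42 * n * stats::runif(1, 0.95, 1.05)   # brain semi-axes
  ay <- 0.36 * n * stats::runif(1, 0.95, 1.05)
  r2 <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2
  brain <- 1 / (1 + exp((r2 - 1) * 40))          # soft brain mask
  vr <- vratio * min(ax, ay)
  rv2 <- ((xs - cx) / vr)^2 + ((ys - cy) / (0.75 * vr))^2
  ventricle <- 1 / (1 + exp((rv2 - 1) * 20))     # soft central ventricle
  img <- brain * (0.62 + 0.18 * phantom_texture(n, freq)) * (1 - 0.85 * ventricle)
  img <- img + stats::rnorm(n * n, sd = noise_sd)
  pmin(pmax(img, 0), 1)
}

#' Generate two-class brain phantoms
#'
#' Draws `2 * n_per_class` slices with class-dependent texture frequency and
#' ventricle size scaled by `effect_size`, grouped into synthetic subjects of
#' `slices_per_subject` slices that share subject-level parameter jitter.
#' Optionally writes PNGs and a `manifest.csv`.
#'
#' @param config A [phantom_config()].
#' @param dir Optional output directory; when given, slices are written as
#'   8-bit grayscale PNGs and the manifest gains a `path` column.
#' @return A list of class `phantom_set`: `images` (array `n x size x size`),
#'   `manifest` (tibble: `path`, `label`, `subject_id`, `segment`,
#'   `orientation`), `config`.
#' @export
generate_phantoms <- function(config = phantom_config(), dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$image_size
  delta <- config$effect_size
  total <- 2L * config$n_per_class
  images <- array(0, dim = c(total, n, n))
  label <- integer(total)
  subject <- character(total)
  segment <- integer(total)
  with_seed(config$seed, {
    i <- 0L
    for (cl in c(0L, 1L)) {
      # class-1 parameters move away from class-0 in proportion to delta
      freq_cl <- config$texture_freq[1] +
        delta * cl * diff(config$texture_freq)
      vr_cl <- config$ventricle_ratio[1] +
        delta * cl * diff(config$ventricle_ratio)
      made <- 0L
      subj_n <- 0L
      while (made < config$n_per_class) {
        subj_n <- subj_n + 1L
        # subject-level jitter shared by the subject's slices
        freq_s <- freq_cl * stats::runif(1, 0.95, 1.05)
        vr_s <- vr_cl * stats::runif(1, 0.92, 1.08)
        k <- min(config$slices_per_subject, config$n_per_class - made)
        for (sl in seq_len(k)) {
          i <- i + 1L
          images[i, , ] <- phantom_slice(n, freq_s * stats::runif(1, 0.98, 1.02),
                                         vr_s * stats::runif(1, 0.97, 1.03),
                                         config$noise_sd)
          label[i] <- cl
          subject[i] <- sprintf("S%d_%03d", cl, subj_n)
          segment[i] <- 3L + sl      # segments 4..(3 + slices_per_subject)
        }
        made <- made + k
      }
    }
  })
  manifest <- tibble::tibble(path = NA_character_, label = label,
                             subject_id = subject, segment = segment,
                             orientation = "axial")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, sprintf("phantom_%s_seg%02d_%04d.png",
                                    subject, segment, seq_len(total)))
    for (i in seq_len(total)) png::writePNG(images[i, , ], paths[i])
    manifest$path <- paths
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(images = images, manifest = manifest, config = config),
            class = "phantom_set")
}

#' Rank slices by intensity entropy
#'
#' Simplified informative-slice selection: each slice is scored by the
#' Shannon entropy (bits) of its 256-bin intensity histogram inside the
#' brain mask (pixels above `mask_threshold`), and slices are ranked from
#' most to least entropic; ties break toward the lower slice index. A
#' constant slice has entropy 0; a slice whose masked histogram is uniform
#' over all 256 bins scores the maximum 8 bits.
#'
#' @param slices Array `(n, H, W)` or list of matrices with values in
#'   `[0, 1]`.
#' @param n_top Optionally return only the `n_top` best slices.
#' @param mask_threshold Pixels at or above this value count as brain
#'   (default 0.05); set to `-Inf` to use every pixel.
#' @return Tibble with `slice`, `entropy` (bits), `rank`, sorted by rank.
#' @export
select_slices_by_entropy <- function(slices, n_top = NULL, mask_threshold = 0.05) {
  if (is.list(slices)) {
    slices <- aperm(simplify2array(slices), c(3, 1, 2))
  }
  stopifnot(length(dim(slices)) == 3)
  n <- dim(slices)[1]
  ent <- vapply(seq_len(n), function(i) {
    v <- slices[i, , ]
    v <- v[v >= mask_threshold]
    if (length(v) == 0) stop(sprintf("slice %d has an empty brain mask", i),
                             call. = FALSE)
    counts <- tabulate(pmin(255L, as.integer(floor(v * 256))) + 1L, nbins = 256L)
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }, numeric(1))
  ord <- order(-ent, seq_len(n))
  out <- tibble::tibble(slice = ord, entropy = ent[ord], rank = seq_len(n))
  if (!is.null(n_top)) out <- out[seq_len(min(n_top, n)), ]
  out
}
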