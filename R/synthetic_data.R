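#' Specification of a synthetic feature bag
#'
#' A bag emulates one slide's mosaic: `n_instances` patch feature vectors of
#' dimension `feature_dim`, of which a fraction `signal_fraction` carry class
#' signal. Signal instances are shifted by plus/minus `class_separation / 2`
#' along a fixed unit direction (all-ones, normalized) according to the bag
#' label; all instances additionally receive isotropic Gaussian noise with
#' standard deviation `noise_scale`. This is the simplest structure under
#' which instance-level attention is identifiable: most instances are
#' uninformative background, as in multiple-instance learning.
#'
#' `n_instances` may be a single count or a `c(min, max)` range, in which case
#' each bag draws its size uniformly from the range (variable-length sets).
#'
#' @param n_instances Positive integer count, or length-2 range.
#' @param feature_dim Positive integer feature dimension f.
#' @param signal_fraction Fraction in (0, 1] of instances carrying signal.
#' @param class_separation Nonnegative mean shift between the two classes.
#' @param noise_scale Positive noise standard deviation.
#' @param seed Integer seed; bags built from the same spec are bit-identical.
#' @return An object of class `bag_spec`.
#' @export
bag_spec <- function(n_instances = c(20L, 50L), feature_dim = 16L,
                     signal_fraction = 0.2, class_separation = 2.0,
                     noise_scale = 1.0, seed = 1L) {
  if (any(n_instances < 1) || length(n_instances) > 2)
    stop("n_instances must be a positive count or a c(min, max) range")
  if (feature_dim < 1) stop("feature_dim must be positive")
  if (signal_fraction <= 0 || signal_fraction > 1)
    stop("signal_fraction must lie in (0, 1]")
  if (class_separation < 0) stop("class_separation must be nonnegative")
  if (noise_scale <= 0) stop("noise_scale must be positive")
  structure(list(n_instances = as.integer(n_instances),
                 feature_dim = as.integer(feature_dim),
                 signal_fraction = signal_fraction,
                 class_separation = class_separation,
                 noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "bag_spec")
}

#' Construct a feature bag
#'
#' @param spec A [bag_spec()].
#' @param label Binary class label (0 or 1).
#' @param bag_id Optional identifier stored on the bag.
#' @return A `feature_bag`: list with `x` (n x f matrix), `label`, `bag_id`.
#' @export
make_bag <- function(spec, label, bag_id = "bag") {
  stopifnot(inherits(spec, "bag_spec"), label %in% c(0, 1))
  with_seed(spec$seed, {
    n <- if (length(spec$n_instances) == 2)
      sample(spec$n_instances[1]:spec$n_instances[2], 1L) else spec$n_instances
    f <- spec$feature_dim
    x <- matrix(stats::rnorm(n * f, sd = spec$noise_scale), n, f)
    n_sig <- ceiling(spec$signal_fraction * n)
    sig_rows <- sample.int(n, n_sig)
    u <- rep(1, f) / sqrt(f)
    shift <- (if (label == 1) 1 else -1) * spec$class_separation / 2
    x[sig_rows, ] <- x[sig_rows, , drop = FALSE] +
      matrix(shift * u, n_sig, f, byrow = TRUE)
    feature_bag(x, label, bag_id)
  })
}

#' Create a feature bag object from a matrix
#' @param x Numeric n x f matrix of instance features.
#' @param label Binary label (0/1) or NA.
#' @param bag_id Identifier string.
#' @export
feature_bag <- function(x, label = NA, bag_id = "bag") {
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("a feature bag needs at least one instance")
  structure(list(x = x, label = label, bag_id = bag_id), class = "feature_bag")
}

#' Specification of a multi-client cohort
#'
#' Mirrors a multi-hospital cohort table: per-client bag counts and class
#' mixes, plus a per-client stain-like covariate shift implemented as one
#' constant vector added to every instance of that client's bags. Class
#' counts may be given either as `n_pos` (exact positive counts) or as
#' `pos_fraction` (rounded to counts).
#'
#' @param clients Character vector of client names.
#' @param n_bags Integer vector of per-client total bag counts (>= 0).
#' @param n_pos Integer vector of per-client positive-class counts, or NULL.
#' @param pos_fraction Per-client positive fractions in `[0, 1]` (used when
#'   `n_pos` is NULL).
#' @param shift_magnitude Per-client domain-shift vector magnitudes (>= 0).
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(clients, n_bags, n_pos = NULL, pos_fraction = 0.5,
                        shift_magnitude = 0, seed = 1L) {
  k <- length(clients)
  n_bags <- as.integer(rep_len(n_bags, k))
  if (any(n_bags < 0)) stop("bag counts must be nonnegative")
  if (is.null(n_pos)) {
    pos_fraction <- rep_len(pos_fraction, k)
    if (any(pos_fraction < 0 | pos_fraction > 1))
      stop("pos_fraction must lie in [0, 1]")
    n_pos <- as.integer(round(pos_fraction * n_bags))
  } else {
    n_pos <- as.integer(rep_len(n_pos, k))
  }
  if (any(n_pos < 0 | n_pos > n_bags)) stop("n_pos must lie in [0, n_bags]")
  structure(list(clients = clients, n_bags = n_bags, n_pos = n_pos,
                 shift_magnitude = rep_len(shift_magnitude, k),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a multi-client cohort of feature bags
#'
#' Each client receives exactly the requested number of bags per class; every
#' instance of a client's bags is shifted by that client's constant
#' domain-shift vector. Per-bag randomness comes from substreams keyed by
#' (client, bag index), so a client's data does not depend on the other
#' clients in the cohort.
#'
#' @param spec A [cohort_spec()].
#' @param bag_spec_template A [bag_spec()] whose seed is replaced per bag.
#' @return A list of `client_dataset` objects (name, bags, shift vector).
#' @export
make_cohort <- function(spec, bag_spec_template) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(bag_spec_template, "bag_spec"))
  f <- bag_spec_template$feature_dim
  lapply(seq_along(spec$clients), function(ci) {
    name <- spec$clients[ci]
    n <- spec$n_bags[ci]
    labels <- c(rep(1L, spec$n_pos[ci]), rep(0L, n - spec$n_pos[ci]))
    shift <- if (spec$shift_magnitude[ci] > 0) {
      v <- with_seed(substream_seed(spec$seed, paste0("shift/", name)),
                     stats::rnorm(f))
      spec$shift_magnitude[ci] * v / sqrt(sum(v^2))
    } else rep(0, f)
    bags <- lapply(seq_len(n), function(bi) {
      bs <- bag_spec_template
      bs$seed <- substream_seed(spec$seed, paste0(name, "/bag-", bi))
      bag <- make_bag(bs, labels[bi], bag_id = sprintf("%s-%03d", name, bi))
      bag$x <- bag$x + matrix(shift, nrow(bag$x), f, byrow = TRUE)
      bag
    })
    structure(list(name = name, bags = bags, shift = shift),
              class = "client_dataset")
  })
}

#' Four-client train/test cohort plus external validation cohort
#'
#' Encodes the hospital-level slide counts of the lung-cancer study this
#' package emulates: four source hospitals acting as federation clients and
#' three external hospitals pooled into a validation cohort. Positive class
#' is adenocarcinoma (LUAD), negative is squamous cell carcinoma (LUSC).
#'
#' @param internal_shift Domain-shift magnitude for the four client hospitals.
#' @param external_shift Domain-shift magnitude for the external hospitals
#'   (larger by default: unseen sites shift more).
#' @param seed Integer seed.
#' @return List with elements `clients` and `external`, both [cohort_spec()]s.
#' @export
hospital_cohort_spec <- function(internal_shift = 0.4, external_shift = 1.2,
                                 seed = 1L) {
  list(
    clients = cohort_spec(
      clients = c("IGC", "Indivumed", "Asterand", "JohnsHopkins"),
      n_bags = c(267L, 211L, 207L, 199L),
      n_pos = c(189L, 94L, 90L, 121L),
      shift_magnitude = internal_shift, seed = seed),
    external = cohort_spec(
      clients = c("Christiana", "RoswellPark", "PrincessMargaret"),
      n_bags = c(223L, 110L, 52L),
      n_pos = c(169L, 35L, 0L),
      shift_magnitude = external_shift,
      seed = substream_seed(seed, "external"))
  )
}

#' Generate a small synthetic tissue-like image
#'
#' Produces an RGB image with a bright background and darker textured
#' "tissue" blobs (random disks with an H&E-like hue), together with the
#' ground-truth tissue mask. When `target_fraction` is given and
#' `n_tissue_blobs > 0`, small top-up blobs are added until the mask covers
#' at least that fraction of the image, so the realized coverage tracks the
#' construction target closely.
#'
#' @param width,height Positive image dimensions in pixels.
#' @param n_tissue_blobs Number of primary blobs (0 gives a blank image).
#' @param seed Integer seed.
#' @param target_fraction Approximate tissue-area fraction, or NULL to place
#'   only the primary blobs.
#' @return List with `image` (height x width x 3 array in `[0, 1]`) and
#'   `mask` (logical height x width matrix of tissue pixels).
#' @export
make_tissue_image <- function(width = 128L, height = 128L, n_tissue_blobs = 5L,
                              seed = 1L, target_fraction = 0.3) {
  if (width < 1 || height < 1) stop("image dimensions must be positive")
  with_seed(seed, {
    mask <- matrix(FALSE, height, width)
    xs <- matrix(rep(seq_len(width), each = height), height, width)
    ys <- matrix(rep(seq_len(height), width), height, width)
    add_blob <- function(mask, r) {
      cx <- stats::runif(1, 1, width); cy <- stats::runif(1, 1, height)
      mask | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
    }
    base_r <- 0.12 * min(width, height)
    for (i in seq_len(n_tissue_blobs))
      mask <- add_blob(mask, base_r * stats::runif(1, 0.6, 1.4))
    if (!is.null(target_fraction) && n_tissue_blobs > 0) {
      topup_r <- max(2, 0.04 * min(width, height))
      guard <- 0
      while (mean(mask) < target_fraction && guard < 10000) {
        mask <- add_blob(mask, topup_r)
        guard <- guard + 1
      }
    }
    npix <- height * width
    img <- array(0, c(height, width, 3))
    bg <- matrix(stats::rnorm(npix, 0.92, 0.015), height, width)
    texture <- matrix(stats::rnorm(npix, 0, 0.05), height, width)
    # H&E-like purple-pink tissue: channel-specific base intensities
    tissue_base <- c(0.55, 0.35, 0.60)
    for (ch in 1:3) {
      plane <- bg
      plane[mask] <- tissue_base[ch] + texture[mask]
      img[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    list(image = img, mask = mask)
  })
}

#' Write a cohort manifest as CSV
#'
#' One row per bag: client, bag_id, label, n_instances.
#'
#' @param cohort List of `client_dataset` objects from [make_cohort()].
#' @param path Output CSV path.
#' @return The manifest data frame, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  rows <- do.call(rbind, lapply(cohort, function(cl) {
    do.call(rbind, lapply(cl$bags, function(b)
      data.frame(client = cl$name, bag_id = b$bag_id, label = b$label,
                 n_instances = nrow(b$x))))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

#' Write feature bags to the flat bag-container CSV format
#'
#' Long format, one row per instance: bag_id, label, instance index, then the
#' feature columns `feat_1 ... feat_f`. [read_bags()] inverts it.
#'
#' @param bags List of `feature_bag` objects.
#' @param path Output CSV path.
#' @export
write_bags <- function(bags, path) {
  rows <- do.call(rbind, lapply(bags, function(b) {
    d <- as.data.frame(b$x)
    names(d) <- paste0("feat_", seq_len(ncol(b$x)))
    cbind(data.frame(bag_id = b$bag_id, label = b$label,
                     instance = seq_len(nrow(b$x))), d)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

#' Read feature bags from the bag-container CSV format
#' @param path CSV path written by [write_bags()].
#' @return List of `feature_bag` objects in file order.
#' @export
read_bags <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  featcols <- grep("^feat_", names(d), value = TRUE)
  ids <- unique(d$bag_id)
  lapply(ids, function(id) {
    sub <- d[d$bag_id == id, , drop = FALSE]
    sub <- sub[order(sub$instance), , drop = FALSE]
    feature_bag(as.matrix(sub[, featcols, drop = FALSE]),
                label = sub$label[1], bag_id = id)
  })
}

# Flatten a cohort (list of client datasets) into bags + labels.
cohort_bags <- function(cohort) {
  bags <- unlist(lapply(cohort, `[[`, "bags"), recursive = FALSE)
  labels <- vapply(bags, `[[`, numeric(1), "label")
  list(bags = bags, labels = labels)
}
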