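# Seeded synthetic chest-radiograph-like data. Images are grayscale
# thorax-like scenes (bright mediastinal ellipse, darker lung fields) on a
# dark background; each positive label adds a class-specific localized
# pattern (blob, streak or texture patch) whose geometry is a deterministic
# hash of the class name, so a class looks the same in every run. Labels
# are per-class Bernoulli draws with optional multiplicative co-occurrence
# odds boosts. None of this is anatomically realistic; it exists so the
# full pipeline (masking, reconstruction, multi-label heads, restructuring
# rules, metrics) is exercisable without any real dataset.

#' Specification for a synthetic radiograph batch
#'
#' @param n_samples number of images (>= 1).
#' @param image_size square image edge in pixels; choose a multiple of the
#'   downstream patch size.
#' @param class_names character vector of label names.
#' @param prevalence per-class marginal probability in \code{[0, 1]}
#'   (recycled if scalar). An imbalanced default with a dominant
#'   "no finding" class mirrors real chest-radiograph label tables.
#' @param cooccurrence optional square matrix of nonnegative odds boosts:
#'   \code{cooccurrence[k, j]} multiplies the odds of class \code{j} when
#'   class \code{k} is already positive (applied sequentially in class
#'   order). \code{NULL} means independent draws.
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param seed integer seed; identical specs give bit-identical batches.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_samples, image_size = 64L,
                           class_names = c("no finding", "opacity", "effusion", "cardiomegaly"),
                           prevalence = c(0.65, 0.2, 0.12, 0.08),
                           cooccurrence = NULL, noise_sd = 0.05, seed = 1L) {
  if (length(image_size) == 2L && image_size[1] != image_size[2])
    stop_currimae("images must be square", "invalid_spec_error")
  image_size <- image_size[1]
  if (n_samples < 1L) stop_currimae("n_samples must be >= 1", "invalid_spec_error")
  if (image_size < 1L) stop_currimae("image_size must be positive", "invalid_spec_error")
  prevalence <- rep_len(prevalence, length(class_names))
  if (any(prevalence < 0) || any(prevalence > 1))
    stop_currimae("prevalence values must lie in [0, 1]", "invalid_spec_error")
  if (!is.null(cooccurrence)) {
    k <- length(class_names)
    if (!is.matrix(cooccurrence) || any(dim(cooccurrence) != k) || any(cooccurrence < 0))
      stop_currimae("cooccurrence must be a nonnegative k x k matrix", "invalid_spec_error")
  }
  structure(list(n_samples = as.integer(n_samples), image_size = as.integer(image_size),
                 class_names = class_names, prevalence = prevalence,
                 cooccurrence = cooccurrence, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Stable small hash of a class name (drives pattern geometry).
class_hash <- function(name) {
  h <- 0L
  for (code in utf8ToInt(name)) h <- (h * 31L + code) %% 1000003L
  h
}

# Draw a multi-label matrix: sequential Bernoulli with odds boosts.
draw_labels <- function(n, prevalence, cooccurrence) {
  k <- length(prevalence)
  y <- matrix(0L, n, k)
  u <- matrix(stats::runif(n * k), n, k)
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      p <- prevalence[j]
      if (!is.null(cooccurrence) && j > 1L) {
        pos <- which(y[i, seq_len(j - 1L)] == 1L)
        if (length(pos) && p > 0 && p < 1) {
          odds <- p / (1 - p) * prod(cooccurrence[pos, j])
          p <- odds / (1 + odds)
        }
      }
      y[i, j] <- as.integer(u[i, j] < p)
    }
  }
  y
}

ellipse_mask <- function(size, cx, cy, rx, ry) {
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  y <- matrix(seq_len(size), size, size)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

# Background anatomy: body ellipse with two darker lung fields.
thorax_background <- function(size) {
  img <- matrix(0.05, size, size)
  img[ellipse_mask(size, size * 0.5, size * 0.55, size * 0.36, size * 0.42)] <- 0.55
  for (cx in c(0.34, 0.66)) {
    img[ellipse_mask(size, size * cx, size * 0.52, size * 0.13, size * 0.28)] <- 0.30
  }
  img
}

# One class-specific pattern stamped into an image (in place semantics via
# return). Geometry is a pure function of the class name.
stamp_pattern <- function(img, name) {
  size <- nrow(img)
  h <- class_hash(name)
  kind <- h %% 3L
  cx <- size * (0.25 + 0.5 * ((h %/% 7L) %% 97L) / 96)
  cy <- size * (0.30 + 0.45 * ((h %/% 11L) %% 89L) / 88)
  if (kind == 0L) {                       # bright blob
    r <- size * (0.05 + 0.06 * ((h %/% 13L) %% 7L) / 6)
    img[ellipse_mask(size, cx, cy, r, r)] <-
      pmin(1, img[ellipse_mask(size, cx, cy, r, r)] + 0.35)
  } else if (kind == 1L) {                # streak
    w <- max(1L, round(size * 0.02))
    len <- round(size * 0.30)
    rows <- pmin(size, pmax(1L, round(cy) + seq(-len %/% 2, len %/% 2)))
    cols <- pmin(size, pmax(1L, round(cx) + seq_len(w) - 1L))
    img[rows, cols] <- pmin(1, img[rows, cols] + 0.30)
  } else {                                # checker texture patch
    r <- round(size * 0.10)
    rows <- pmin(size, pmax(1L, round(cy) + seq(-r, r)))
    cols <- pmin(size, pmax(1L, round(cx) + seq(-r, r)))
    tex <- 0.25 * ((outer(rows, cols, `+`) %% 2L))
    img[rows, cols] <- pmin(1, img[rows, cols] + tex)
  }
  img
}

#' Render radiograph-like images for a given label matrix
#'
#' Deterministic given the current RNG state: background anatomy, one
#' stamped pattern per positive label (skipping any class named
#' "no finding"), then clipped Gaussian noise.
#'
#' @param labels binary matrix (samples x classes) with column names.
#' @param image_size square edge in pixels.
#' @param noise_sd Gaussian noise standard deviation.
#' @return array \code{n x image_size x image_size} with intensities in
#'   \code{[0, 1]}.
#' @export
render_cxr_images <- function(labels, image_size, noise_sd = 0.05) {
  classes <- colnames(labels)
  n <- nrow(labels)
  bg <- thorax_background(image_size)
  imgs <- array(0, c(n, image_size, image_size))
  for (i in seq_len(n)) {
    img <- bg
    for (j in which(labels[i, ] == 1L)) {
      if (identical(tolower(classes[j]), "no finding")) next
      img <- stamp_pattern(img, classes[j])
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(image_size^2, 0, noise_sd), image_size)
    imgs[i, , ] <- pmin(1, pmax(0, img))
  }
  imgs
}

#' Generate a synthetic radiograph batch
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return object of class \code{synthetic_batch}: \code{images}
#'   (\code{n x s x s} array in \code{[0, 1]}), \code{labels} (binary
#'   matrix with the spec's class names), and \code{manifest}
#'   (\code{sample_id}, \code{path} (NA until written), \code{view} =
#'   "frontal").
#' @export
generate_cxr_like <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop_currimae("spec must be a synthetic_spec", "invalid_spec_error")
  set.seed(spec$seed)
  labels <- draw_labels(spec$n_samples, spec$prevalence, spec$cooccurrence)
  colnames(labels) <- spec$class_names
  images <- render_cxr_images(labels, spec$image_size, spec$noise_sd)
  ids <- sprintf("syn%05d", seq_len(spec$n_samples))
  rownames(labels) <- ids
  structure(list(images = images, labels = labels,
                 manifest = data.frame(sample_id = ids, path = NA_character_,
                                       view = "frontal",
                                       stringsAsFactors = FALSE)),
            class = "synthetic_batch")
}

#' Write a synthetic batch to disk
#'
#' Images as 8-bit grayscale PNGs plus a manifest CSV with header
#' \code{sample_id,path,view,<class columns>} (labels as 0/1 integers).
#'
#' @param batch a \code{synthetic_batch}.
#' @param dir output directory.
#' @param origin dataset-origin tag recorded in the manifest.
#' @return data.frame manifest (also written to \code{manifest.csv}),
#'   invisibly.
#' @export
write_synthetic_dataset <- function(batch, dir, origin = "synthetic") {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  n <- nrow(batch$labels)
  paths <- file.path(dir, "images", paste0(batch$manifest$sample_id, ".png"))
  for (i in seq_len(n)) png::writePNG(batch$images[i, , ], paths[i])
  man <- data.frame(sample_id = batch$manifest$sample_id, path = paths,
                    origin = origin, view = batch$manifest$view,
                    stringsAsFactors = FALSE)
  man <- cbind(man, as.data.frame(batch$labels, row.names = NULL))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Canonical 15-class pediatric label schema
#'
#' The raw pediatric training table carries fifteen disease classes: six
#' that survive restructuring (no finding, bronchitis, broncho-pneumonia,
#' bronchiolitis, pneumonia, other diseases), four absent from the test
#' split (congenital emphysema, diaphragmatic hernia, lung tumor,
#' pleuro-pneumonia) and five with fewer than twenty training positives
#' (CPAM, hyaline membrane disease, mediastinal tumor, situs inversus,
#' tuberculosis).
#'
#' @return named list with \code{core}, \code{absent_in_test},
#'   \code{rare_in_train}, and \code{all} (the 15 names in order).
#' @export
pedicxr_schema <- function() {
  core <- c("no finding", "bronchitis", "broncho-pneumonia",
            "bronchiolitis", "pneumonia", "other diseases")
  absent <- c("congenital emphysema", "diaphragmatic hernia",
              "lung tumor", "pleuro-pneumonia")
  rare <- c("CPAM", "hyaline membrane disease", "mediastinal tumor",
            "situs inversus", "tuberculosis")
  list(core = core, absent_in_test = absent, rare_in_train = rare,
       all = c(core, absent, rare))
}

#' Generate raw 15-class pediatric-style label tables
#'
#' Produces train and test tables over the \code{\link{pedicxr_schema}}
#' classes with the structural properties the restructuring rules rely on:
#' the four absent-in-test classes have zero test positives, and each of
#' the five rare classes has between 1 and 19 training positives. Marginal
#' class frequencies approximate the real pediatric table (about 65\%
#' "no finding").
#'
#' @param n_train training rows (>= 100, so the rare-class counts fit).
#' @param n_test test rows (>= 1).
#' @param seed integer seed.
#' @return list with \code{train} and \code{test}, each a
#'   \code{\link{label_table}} with split tags "train" / "test".
#' @export
generate_pedicxr_raw_labels <- function(n_train = 7728L, n_test = 1398L, seed = 1L) {
  if (n_train < 100L)
    stop_currimae("n_train must be >= 100 to satisfy the rare-class constraint",
                  "invalid_spec_error")
  if (n_test < 1L) stop_currimae("n_test must be >= 1", "invalid_spec_error")
  sch <- pedicxr_schema()
  set.seed(seed)
  make_table <- function(n, prefix, is_test) {
    y <- matrix(0L, n, 15L, dimnames = list(NULL, sch$all))
    # dominant healthy class; diseased rows draw among the core diseases
    healthy <- stats::runif(n) < 0.655
    y[healthy, "no finding"] <- 1L
    sick <- which(!healthy)
    core_p <- c("bronchitis" = 0.33, "broncho-pneumonia" = 0.21,
                "bronchiolitis" = 0.19, "pneumonia" = 0.15, "other diseases" = 0.12)
    for (cl in names(core_p)) y[sick, cl] <- as.integer(stats::runif(length(sick)) < core_p[cl])
    # any diseased row left without a label becomes "other diseases"
    none <- sick[rowSums(y[sick, names(core_p), drop = FALSE]) == 0L]
    y[none, "other diseases"] <- 1L
    # the real table's core classes all clear the rarity threshold by a wide
    # margin (>= hundreds of train and tens of test positives); preserve that
    # structural property at reduced n by topping thin classes up
    floor_n <- if (is_test) min(3L, length(sick)) else min(21L, length(sick))
    for (cl in names(core_p)) {
      short <- floor_n - sum(y[sick, cl])
      if (short > 0L) {
        without <- sick[y[sick, cl] == 0L]
        y[without[sample.int(length(without), min(short, length(without)))], cl] <- 1L
      }
    }
    if (!is_test) {
      for (cl in sch$absent_in_test) {
        k <- sample(20:60, 1L)
        y[sick[sample.int(length(sick), min(k, length(sick)))], cl] <- 1L
      }
      for (cl in sch$rare_in_train) {
        k <- sample(1:19, 1L)
        y[sick[sample.int(length(sick), min(k, length(sick)))], cl] <- 1L
      }
    } else {
      # rare-in-train classes may appear in the test split in small numbers
      for (cl in sch$rare_in_train) {
        k <- sample(0:5, 1L)
        if (k > 0L && length(sick) > 0L)
          y[sick[sample.int(length(sick), min(k, length(sick)))], cl] <- 1L
      }
    }
    label_table(ids = sprintf("%s%05d", prefix, seq_len(n)), labels = y,
                split = if (is_test) "test" else "train")
  }
  list(train = make_table(n_train, "ped-tr-", FALSE),
       test = make_table(n_test, "ped-te-", TRUE))
}
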