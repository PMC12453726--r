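# Manifests, label tables, the frontal-view filter, the 15-to-6 class
# restructuring rule, the 80/20 split, and image loading/augmentation.

#' Multi-label table with split tags
#'
#' @param ids character sample ids (unique).
#' @param labels binary matrix (samples x classes) with unique column names.
#' @param split split tag per sample in \{train, val, test\} (recycled).
#' @return object of class \code{label_table}.
#' @export
label_table <- function(ids, labels, split = "train") {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (anyDuplicated(ids)) stop_currimae("sample ids must be unique", "schema_error")
  if (is.null(colnames(labels)) || anyDuplicated(colnames(labels)))
    stop_currimae("label columns must be uniquely named", "schema_error")
  if (nrow(labels) != length(ids))
    stop_currimae("label row count must equal id count", "schema_error")
  if (!all(labels %in% c(0L, 1L)))
    stop_currimae("label entries must be 0/1", "schema_error")
  split <- rep_len(split, length(ids))
  if (!all(split %in% c("train", "val", "test")))
    stop_currimae("split tags must be train/val/test", "schema_error")
  rownames(labels) <- ids
  structure(list(ids = as.character(ids), classes = colnames(labels),
                 labels = labels, split = split),
            class = "label_table")
}

#' @export
print.label_table <- function(x, ...) {
  cat(sprintf("<label_table: %d samples x %d classes; splits: %s>\n",
              length(x$ids), length(x$classes),
              paste(sprintf("%s=%d", names(table(x$split)), table(x$split)),
                    collapse = ", ")))
  invisible(x)
}

#' Build the pretraining manifest from multiple sources
#'
#' Concatenates source manifests after discarding every non-frontal row
#' (lateral radiographs are excluded from pretraining). Label columns are
#' not required: pretraining is unsupervised.
#'
#' @param sources list of data.frames, each with at least
#'   \code{sample_id}, \code{path}, \code{origin}, \code{view} columns;
#'   \code{view} is "frontal" or "lateral".
#' @return data.frame containing only the surviving frontal rows; a warning
#'   (not an error) is raised when nothing survives.
#' @export
build_pretrain_manifest <- function(sources) {
  if (is.data.frame(sources)) sources <- list(sources)
  need <- c("sample_id", "path", "origin", "view")
  for (s in sources)
    if (!all(need %in% names(s)))
      stop_currimae(paste("manifest sources need columns:", paste(need, collapse = ", ")),
                    "schema_error")
  all_rows <- do.call(rbind, lapply(sources, function(s) s[, need]))
  dup <- all_rows$sample_id[duplicated(all_rows$sample_id)]
  if (length(dup))
    stop_currimae(paste("duplicate sample ids across sources:",
                        paste(utils::head(unique(dup), 5L), collapse = ", ")),
                  "duplication_error")
  out <- all_rows[all_rows$view == "frontal", , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no frontal rows survived the view filter")
  out
}

#' Read / write a manifest CSV
#'
#' Header \code{sample_id,path,origin,view,<label columns>}.
#' @param path CSV path.
#' @param check_paths verify every referenced image exists.
#' @return data.frame.
#' @export
read_manifest <- function(path, check_paths = FALSE) {
  if (!file.exists(path)) stop_currimae(paste("no manifest at", path), "io_error")
  man <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(man$sample_id))
    stop_currimae("manifest sample ids are not unique", "duplication_error")
  if (check_paths && !all(file.exists(man$path)))
    stop_currimae("manifest references missing image files", "io_error")
  man
}

#' @rdname read_manifest
#' @param man manifest data.frame.
#' @export
write_manifest <- function(man, path) {
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Restructure a raw 15-class pediatric label table to six classes
#'
#' Classes with zero positives in the test table, and classes with fewer
#' than \code{min_train_count} positives in the train table, are OR-merged
#' into "other diseases"; the protected classes "no finding" and
#' "other diseases" are never merged away. The output schema is exactly
#' \code{no finding, bronchitis, broncho-pneumonia, bronchiolitis,
#' pneumonia, other diseases}, in that order. Every original positive maps
#' into exactly one final column, so no label is dropped.
#'
#' @param train,test \code{\link{label_table}}s sharing one schema that
#'   contains "no finding" and "other diseases".
#' @param min_train_count merge threshold on training positives
#'   (default 20).
#' @return list with restructured \code{train} and \code{test} tables.
#' @export
restructure_pedicxr_labels <- function(train, test, min_train_count = 20L) {
  if (!identical(train$classes, test$classes))
    stop_currimae("train and test tables must share one class schema", "schema_error")
  cls <- train$classes
  if (!all(c("no finding", "other diseases") %in% cls))
    stop_currimae("schema must contain 'no finding' and 'other diseases'", "schema_error")
  protected <- c("no finding", "other diseases")
  train_pos <- colSums(train$labels)
  test_pos <- colSums(test$labels)
  mergeable <- setdiff(cls, protected)
  merged <- mergeable[test_pos[mergeable] == 0L | train_pos[mergeable] < min_train_count]
  kept <- setdiff(cls, merged)
  final <- intersect(c("no finding", "bronchitis", "broncho-pneumonia",
                       "bronchiolitis", "pneumonia", "other diseases"), kept)
  final <- c(final, setdiff(kept, final))     # any extra retained class keeps a column
  squash <- function(tab) {
    y <- tab$labels[, final, drop = FALSE]
    if (length(merged))
      y[, "other diseases"] <- as.integer(
        y[, "other diseases"] | rowSums(tab$labels[, merged, drop = FALSE]) > 0L)
    label_table(tab$ids, y, tab$split)
  }
  list(train = squash(train), test = squash(test), merged_classes = merged)
}

#' Split a training table into train and validation
#'
#' Seeded uniform shuffle (no stratification):
#' \code{round(train_fraction * n)} rows keep the "train" tag, the rest
#' become "val".
#'
#' @param table a \code{\link{label_table}} whose rows are all tagged
#'   "train".
#' @param train_fraction fraction kept for training, in (0, 1);
#'   default 0.8.
#' @param seed integer seed.
#' @return the table with reassigned split tags.
#' @export
split_train_val <- function(table, train_fraction = 0.8, seed = 1L) {
  n <- length(table$ids)
  if (n < 2L) stop_currimae("need at least 2 rows to split", "cannot_split_error")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_currimae("train_fraction must lie in (0, 1)", "invalid_spec_error")
  if (!all(table$split == "train"))
    stop_currimae("all rows must be tagged 'train' before splitting", "schema_error")
  set.seed(seed)
  n_train <- round_half_up(train_fraction * n)
  ord <- sample.int(n)
  split <- rep("val", n)
  split[ord[seq_len(n_train)]] <- "train"
  table$split <- split
  table
}

#' Subset a label table by split tag
#' @param table a \code{\link{label_table}}.
#' @param which split tag to keep.
#' @return a \code{label_table}.
#' @export
filter_split <- function(table, which) {
  keep <- table$split == which
  label_table(table$ids[keep], table$labels[keep, , drop = FALSE],
              table$split[keep])
}

# ---- augmentation -----------------------------------------------------------

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Augmentation configuration
#'
#' The pretraining recipe is deliberately weak: resize, crop, horizontal
#' flip, then per-channel standardization with ImageNet statistics
#' (grayscale input is replicated to three channels first). Training
#' phases take a random crop and random flip; the eval phase takes a
#' deterministic center crop and never flips.
#'
#' @param resize_to edge after resizing (default 256).
#' @param crop_to edge after cropping (default 224); must not exceed
#'   \code{resize_to}.
#' @param horizontal_flip_prob flip probability for training phases.
#' @param normalize_mean,normalize_sd per-channel statistics.
#' @param phase one of "pretrain", "finetune", "eval".
#' @param randaug_n,randaug_magnitude RandAugment ops per image and
#'   magnitude (0--10); applied only in the finetune phase.
#' @return object of class \code{augmentation_config}.
#' @export
augmentation_config <- function(resize_to = 256L, crop_to = 224L,
                                horizontal_flip_prob = 0.5,
                                normalize_mean = IMAGENET_MEAN,
                                normalize_sd = IMAGENET_SD,
                                phase = c("pretrain", "finetune", "eval"),
                                randaug_n = 2L, randaug_magnitude = 6) {
  phase <- match.arg(phase)
  if (crop_to > resize_to)
    stop_currimae("crop_to must not exceed resize_to", "invalid_spec_error")
  if (horizontal_flip_prob < 0 || horizontal_flip_prob > 1)
    stop_currimae("flip probability must lie in [0, 1]", "invalid_spec_error")
  structure(list(resize_to = as.integer(resize_to), crop_to = as.integer(crop_to),
                 horizontal_flip_prob = horizontal_flip_prob,
                 normalize_mean = normalize_mean, normalize_sd = normalize_sd,
                 phase = phase, randaug_n = as.integer(randaug_n),
                 randaug_magnitude = randaug_magnitude),
            class = "augmentation_config")
}

read_gray_image <- function(path) {
  if (!file.exists(path))
    stop_currimae(paste("cannot read image:", path), "io_error")
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop_currimae(
                    paste("corrupt or unreadable image:", path), "io_error"))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3L, dim(img)[3])], c(1, 2), mean)
  img
}

resize_gray <- function(img, to) {
  if (nrow(img) == to && ncol(img) == to) return(img)
  as.matrix(EBImage::resize(EBImage::Image(img), w = to, h = to))
}

hflip_chw <- function(x) x[, , dim(x)[3]:1, drop = FALSE]

#' Load and augment one image
#'
#' Reads a grayscale (or RGB, averaged) image, replicates it to three
#' channels, resizes, crops, optionally flips, and standardizes channels.
#' With \code{phase = "eval"} the result is a pure function of the file
#' content. An in-memory matrix may be passed instead of a path.
#'
#' @param image file path or numeric matrix in \code{[0, 1]}.
#' @param config an \code{\link{augmentation_config}}.
#' @return numeric array \code{3 x crop_to x crop_to}.
#' @export
load_and_augment <- function(image, config) {
  img <- if (is.character(image)) read_gray_image(image) else image
  img <- resize_gray(img, config$resize_to)
  train_phase <- config$phase %in% c("pretrain", "finetune")
  if (config$phase == "finetune" && config$randaug_n > 0L)
    img <- rand_augment(img, config$randaug_n, config$randaug_magnitude)
  off_max <- config$resize_to - config$crop_to
  if (off_max > 0L) {
    if (train_phase) {
      oy <- sample.int(off_max + 1L, 1L) - 1L
      ox <- sample.int(off_max + 1L, 1L) - 1L
    } else {
      oy <- ox <- off_max %/% 2L
    }
    img <- img[(oy + 1L):(oy + config$crop_to), (ox + 1L):(ox + config$crop_to)]
  }
  x <- array(rep(img, 3L), c(config$crop_to, config$crop_to, 3L))
  x <- aperm(x, c(3, 1, 2))                      # channels first
  if (train_phase && stats::runif(1) < config$horizontal_flip_prob)
    x <- hflip_chw(x)
  sweep(sweep(x, 1, config$normalize_mean, `-`), 1, config$normalize_sd, `/`)
}

# ---- RandAugment (grayscale-safe subset) ------------------------------------
# Two randomly chosen ops per image at a shared magnitude (0-10). The op
# set keeps geometric translations/rotation plus photometric ops that make
# sense on replicated-grayscale radiographs; hue/color ops are pointless
# here and omitted.

ra_translate <- function(img, frac, axis) {
  n <- nrow(img)
  k <- round(frac * n)
  if (k == 0L) return(img)
  out <- img
  if (axis == 1L) {
    if (k > 0) out <- rbind(img[rep(1L, k), , drop = FALSE], img[1:(n - k), , drop = FALSE])
    else out <- rbind(img[(1 - k):n, , drop = FALSE], img[rep(n, -k), , drop = FALSE])
  } else {
    if (k > 0) out <- cbind(img[, rep(1L, k), drop = FALSE], img[, 1:(n - k), drop = FALSE])
    else out <- cbind(img[, (1 - k):n, drop = FALSE], img[, rep(n, -k), drop = FALSE])
  }
  out
}

ra_rotate <- function(img, degrees) {
  as.matrix(EBImage::rotate(EBImage::Image(img), degrees,
                            output.dim = c(nrow(img), ncol(img)), bg.col = 0))
}

rand_augment <- function(img, n_ops = 2L, magnitude = 6) {
  m <- magnitude / 10
  ops <- c("identity", "translate_x", "translate_y", "rotate",
           "brightness", "contrast", "solarize", "posterize")
  for (op in sample(ops, n_ops, replace = TRUE)) {
    sgn <- sample(c(-1, 1), 1L)
    img <- switch(op,
      identity = img,
      translate_x = ra_translate(img, sgn * 0.3 * m, 2L),
      translate_y = ra_translate(img, sgn * 0.3 * m, 1L),
      rotate = as.matrix(ra_rotate(img, sgn * 30 * m)),
      brightness = clamp01(img + sgn * 0.4 * m),
      contrast = clamp01((img - mean(img)) * (1 + sgn * 0.8 * m) + mean(img)),
      solarize = ifelse(img > 1 - 0.6 * m, 1 - img, img),
      posterize = round(img * (2^max(1, round(8 - 6 * m)))) / (2^max(1, round(8 - 6 * m)))
    )
  }
  img
}
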