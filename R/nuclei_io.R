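# Ingestion of per-block nuclei segmentation output and consolidation into
# slide-global coordinates with the three-category class merging.

RAW_CLASSES <- c("neoplastic", "non_neoplastic_epithelial", "inflammatory",
                 "connective", "dead", "non_nuclei")
MERGED_CLASSES <- c("neoplastic", "inflammatory", "miscellaneous")

# Fixed raw -> merged mapping: non-nuclei dropped; non-neoplastic epithelial,
# connective and dead collapse into "miscellaneous".
MERGE_TABLE <- c(neoplastic = "neoplastic",
                 non_neoplastic_epithelial = "miscellaneous",
                 inflammatory = "inflammatory",
                 connective = "miscellaneous",
                 dead = "miscellaneous",
                 non_nuclei = NA_character_)

#' Default integer type-id table for segmentation output
#'
#' Maps the integer `type` ids of HoVer-Net-style per-block JSON to raw
#' PanNuke class names. The default follows the PanNuke checkpoint
#' convention (0 = non-nuclei/background, 1 = neoplastic, 2 = inflammatory,
#' 3 = connective, 4 = dead, 5 = non-neoplastic epithelial). Tool versions
#' differ, so the table is an argument everywhere it is consumed.
#'
#' @return Named character vector; names are the integer ids as strings.
#' @export
default_type_table <- function() {
  c("0" = "non_nuclei", "1" = "neoplastic", "2" = "inflammatory",
    "3" = "connective", "4" = "dead", "5" = "non_neoplastic_epithelial")
}

#' Construct a nuclei table
#'
#' @param records data.frame with columns `centroid_x`, `centroid_y`,
#'   `raw_class` and/or `merged_class` (0-based pixel coordinates,
#'   x = column, y = row).
#' @param slide_width,slide_height slide dimensions in pixels.
#' @param mpp microns per pixel (nominal 0.50 at 20x).
#' @param mapped logical; `TRUE` once classes have been merged.
#' @return An object of class `nuclei_table`.
#' @export
nuclei_table <- function(records, slide_width, slide_height, mpp = 0.5,
                         mapped = FALSE) {
  stopifnot(is.data.frame(records))
  if (slide_width <= 0 || slide_height <= 0)
    stop("slide dimensions must be positive")
  if (nrow(records) > 0) {
    if (any(records$centroid_x < 0) || any(records$centroid_x >= slide_width) ||
        any(records$centroid_y < 0) || any(records$centroid_y >= slide_height))
      stop("nucleus centroid outside slide bounds")
  }
  structure(list(records = records, slide_width = slide_width,
                 slide_height = slide_height, mpp = mpp, mapped = mapped),
            class = "nuclei_table")
}

#' @export
print.nuclei_table <- function(x, ...) {
  cat(sprintf("nuclei_table: %d nuclei on a %d x %d px slide (%.2f um/px)\n",
              nrow(x$records), x$slide_width, x$slide_height, x$mpp))
  cls <- if (x$mapped) "merged_class" else "raw_class"
  if (nrow(x$records) > 0 && cls %in% names(x$records))
    print(table(x$records[[cls]]))
  invisible(x)
}

#' Define a slide block
#'
#' Blocks tile the slide half-open as `[origin, origin + block_size)`;
#' origins are multiples of the block size. Ragged edge blocks are clipped
#' to the slide bounds downstream.
#'
#' @param origin_x,origin_y block origin in pixels (0-based).
#' @param block_size block edge length in pixels (default 8000).
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(origin_x, origin_y, block_size = 8000) {
  if (block_size <= 0) stop("block_size must be positive")
  if (origin_x %% block_size != 0 || origin_y %% block_size != 0)
    stop("block origins must be multiples of block_size")
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 block_size = block_size), class = "block_spec")
}

#' Read one block of nuclei segmentation output
#'
#' Parses the documented per-block JSON dialect: an object mapping
#' nucleus id to `{"centroid": [x, y], "type": <int>}` (an enclosing
#' `"nuc"` wrapper, as emitted by some tool versions, is tolerated).
#' Centroids are returned in block-local coordinates; stitching into the
#' slide frame is a separate step.
#'
#' @param path path to the block JSON file.
#' @param block a [block_spec()] describing the block's place in the slide.
#' @param type_table integer-id to raw-class table; see
#'   [default_type_table()].
#' @return A `nuclei_table` whose slide dimensions are the block's own
#'   (clipped) extent and whose coordinates are block-local.
#' @export
read_block_nuclei <- function(path, block, type_table = default_type_table()) {
  if (!file.exists(path)) stop("block file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("unparseable block JSON '", path,
                                           "': ", conditionMessage(e)))
  if (!is.null(obj$nuc)) obj <- obj$nuc
  n <- length(obj)
  if (n == 0) {
    rec <- data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
                      raw_class = character(0))
  } else {
    cx <- numeric(n); cy <- numeric(n); ty <- character(n)
    for (i in seq_len(n)) {
      nd <- obj[[i]]
      if (is.null(nd$centroid) || length(nd$centroid) < 2 || is.null(nd$type))
        stop("malformed nucleus entry in '", path, "'")
      cx[i] <- as.numeric(nd$centroid[[1]])
      cy[i] <- as.numeric(nd$centroid[[2]])
      ty[i] <- as.character(nd$type)
    }
    unknown <- setdiff(unique(ty), names(type_table))
    if (length(unknown) > 0)
      stop("unknown nucleus type id(s): ", paste(unknown, collapse = ", "))
    rec <- data.frame(centroid_x = cx, centroid_y = cy,
                      raw_class = unname(type_table[ty]))
  }
  nuclei_table(rec, slide_width = block$block_size,
               slide_height = block$block_size)
}

#' Read a block manifest
#'
#' The manifest CSV lists one row per block: `file`, `origin_x`, `origin_y`.
#' Paths are taken relative to the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param block_size block edge length in pixels.
#' @return list with elements `paths` and `blocks` (list of [block_spec()]).
#' @export
read_block_manifest <- function(path, block_size = 8000) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "origin_x", "origin_y")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  blocks <- lapply(seq_len(nrow(man)), function(i)
    block_spec(man$origin_x[i], man$origin_y[i], block_size))
  list(paths = file.path(dirname(path), man$file), blocks = blocks)
}

#' Stitch block-local nuclei tables into slide coordinates
#'
#' Offsets each table's centroids by its block origin and concatenates.
#' Record counts are conserved; a centroid that lands outside the stated
#' slide bounds is an error (the upstream tool mis-assigned the block).
#'
#' @param tables list of `nuclei_table` in block-local coordinates.
#' @param blocks list of [block_spec()], one per table.
#' @param slide_width,slide_height full slide dimensions in pixels.
#' @param mpp microns per pixel.
#' @return A consolidated `nuclei_table` in slide-global coordinates.
#' @export
stitch_blocks <- function(tables, blocks, slide_width, slide_height,
                          mpp = 0.5) {
  if (length(tables) != length(blocks))
    stop("one block_spec per table required")
  parts <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    rec <- tables[[i]]$records
    if (nrow(rec) > 0) {
      rec$centroid_x <- rec$centroid_x + blocks[[i]]$origin_x
      rec$centroid_y <- rec$centroid_y + blocks[[i]]$origin_y
    }
    parts[[i]] <- rec
  }
  all_rec <- do.call(rbind, parts)
  if (is.null(all_rec))
    all_rec <- data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
                          raw_class = character(0))
  if (nrow(all_rec) > 0 &&
      (any(all_rec$centroid_x >= slide_width) ||
       any(all_rec$centroid_y >= slide_height)))
    stop("stitched centroid outside slide bounds")
  nuclei_table(all_rec, slide_width, slide_height, mpp = mpp)
}

#' Merge the six raw PanNuke classes into three categories
#'
#' Drops non-nuclei records; maps neoplastic to neoplastic, inflammatory to
#' inflammatory, and non-neoplastic epithelial / connective / dead to a
#' consolidated "miscellaneous" category. Idempotent on already-mapped
#' tables.
#'
#' @param table a `nuclei_table` with `raw_class` assigned (or an
#'   already-mapped table, returned unchanged).
#' @return A mapped `nuclei_table` with a `merged_class` column.
#' @export
map_classes <- function(table) {
  stopifnot(inherits(table, "nuclei_table"))
  if (isTRUE(table$mapped)) return(table)
  rec <- table$records
  if (!"raw_class" %in% names(rec))
    stop("table has no raw_class column; nothing to map")
  if (nrow(rec) > 0 && !all(rec$raw_class %in% RAW_CLASSES))
    stop("unknown raw class label(s): ",
         paste(setdiff(unique(rec$raw_class), RAW_CLASSES), collapse = ", "))
  merged <- unname(MERGE_TABLE[rec$raw_class])
  keep <- !is.na(merged)
  out <- rec[keep, c("centroid_x", "centroid_y"), drop = FALSE]
  out$merged_class <- factor(merged[keep], levels = MERGED_CLASSES)
  rownames(out) <- NULL
  nuclei_table(out, table$slide_width, table$slide_height, mpp = table$mpp,
               mapped = TRUE)
}

#' Write / read a consolidated nuclei table as CSV
#'
#' @param table a mapped `nuclei_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nuclei_csv <- function(table, path) {
  stopifnot(inherits(table, "nuclei_table"), isTRUE(table$mapped))
  rec <- table$records
  rec$merged_class <- as.character(rec$merged_class)
  hdr <- sprintf("# slide_width=%d slide_height=%d mpp=%g",
                 table$slide_width, table$slide_height, table$mpp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(rec, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nuclei_csv
#' @export
read_nuclei_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.]+", hdr))[[1]]
  meta <- setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  rec <- read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  rec$merged_class <- factor(rec$merged_class, levels = MERGED_CLASSES)
  nuclei_table(rec, meta[["slide_width"]], meta[["slide_height"]],
               mpp = meta[["mpp"]], mapped = TRUE)
}
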