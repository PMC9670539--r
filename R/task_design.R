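# Task construction: jars, series, blocks.
#
# Symbol conventions used throughout the package:
#   neutral content   -> beads coloured "red" (jar A dominant) / "green" (jar B dominant)
#   emotional content -> faces "happy" (village A dominant) / "angry" (village B dominant)
# The fixed neutral -> emotional symbol map is red -> happy, green -> angry.

.SYMBOLS <- list(
  neutral   = c(A = "red",   B = "green"),
  emotional = c(A = "happy", B = "angry")
)
.SYMBOL_MAP <- c(red = "happy", green = "angry")

.JAR_RATIOS <- c("80:20", "60:40")
.CONTENTS <- c("neutral", "emotional")

#' Symbols used by a content condition
#'
#' @param content `"neutral"` or `"emotional"`.
#' @return Named character vector with elements `A` (jar A's dominant symbol)
#'   and `B` (jar B's dominant symbol).
#' @export
task_symbols <- function(content = c("neutral", "emotional")) {
  content <- match.arg(content)
  .SYMBOLS[[content]]
}

#' Define a mirrored pair of jars
#'
#' The two containers of a condition are exact mirrors: jar A's dominant
#' symbol is jar B's minority symbol and vice versa.
#'
#' @param p_dominant Proportion of the majority symbol in each jar,
#'   in (0.5, 1].
#' @param content Content condition; determines the symbol alphabet.
#' @return A list with elements `A` and `B`, each a `jar_spec` list with
#'   fields `label`, `p_dominant` and `dominant_color`.
#' @examples
#' jar_pair(0.8)           # 80:20 bead jars
#' jar_pair(0.6, "emotional")
#' @export
jar_pair <- function(p_dominant, content = c("neutral", "emotional")) {
  content <- match.arg(content)
  if (!is.numeric(p_dominant) || length(p_dominant) != 1L ||
      p_dominant <= 0.5 || p_dominant > 1) {
    stop("`p_dominant` must be a single number in (0.5, 1]", call. = FALSE)
  }
  sym <- .SYMBOLS[[content]]
  structure(list(
    A = structure(list(label = "A", p_dominant = p_dominant,
                       dominant_color = unname(sym["A"])), class = "jar_spec"),
    B = structure(list(label = "B", p_dominant = p_dominant,
                       dominant_color = unname(sym["B"])), class = "jar_spec"),
    content = content
  ), class = "jar_pair")
}

#' Canonical composition of the seven series
#'
#' Series are indexed 1-7; each composition gives the counts of the
#' (jar-A-dominant, jar-B-dominant) symbols out of 10 draws. In neutral terms
#' these are red:green counts. Series 6/7 realise the jar ratios of the 80:20
#' block, series 1/4 those of the 60:40 block; series 2 (100:0), 5 (0:100)
#' and 3 (50:50) are shared between blocks. The assignment of ids 2 and 3 is
#' a convention and can be overridden through the `series_map` argument of
#' [build_canonical_task()].
#'
#' @return Named list mapping series id (as character) to an integer pair
#'   `c(n_A, n_B)`.
#' @export
canonical_series_map <- function() {
  list(`1` = c(6L, 4L), `2` = c(10L, 0L), `3` = c(5L, 5L), `4` = c(4L, 6L),
       `5` = c(0L, 10L), `6` = c(8L, 2L), `7` = c(2L, 8L))
}

.block_series_ids <- function(jar_ratio) {
  # order: jar-A ratio, jar-B ratio, 100:0, 0:100, 50:50
  if (jar_ratio == "80:20") c(6L, 7L, 2L, 5L, 3L) else c(1L, 4L, 2L, 5L, 3L)
}

.ratio_p <- function(jar_ratio) if (jar_ratio == "80:20") 0.8 else 0.6

.check_series_map <- function(series_map) {
  canonical <- canonical_series_map()
  if (!is.list(series_map) || is.null(names(series_map))) {
    stop("`series_map` must be a named list of integer pairs", call. = FALSE)
  }
  ids <- names(series_map)
  if (anyDuplicated(ids)) stop("duplicate series ids in `series_map`", call. = FALSE)
  if (!setequal(ids, names(canonical))) {
    stop("`series_map` must assign compositions to series ids 1-7", call. = FALSE)
  }
  comps <- lapply(series_map, function(x) as.integer(x))
  for (id in ids) {
    cmp <- comps[[id]]
    if (length(cmp) != 2L || any(cmp < 0L) || sum(cmp) != 10L) {
      stop(sprintf("series %s: composition must be two non-negative counts summing to 10", id),
           call. = FALSE)
    }
  }
  declared <- vapply(comps, paste, "", collapse = ":")
  wanted <- vapply(canonical, paste, "", collapse = ":")
  if (!setequal(declared, wanted)) {
    stop("`series_map` compositions must be a permutation of the declared set ",
         "{6:4, 4:6, 8:2, 2:8, 10:0, 0:10, 5:5}", call. = FALSE)
  }
  comps
}

.make_series <- function(series_id, composition, content, jar_ratio, draws) {
  structure(list(
    series_id = as.integer(series_id),
    declared_ratio = as.integer(composition),
    draws = draws,
    content = content,
    jar_ratio_condition = jar_ratio
  ), class = "series_spec")
}

#' Build the canonical four-block task
#'
#' Constructs the full design: blocks in fixed order (neutral 80:20, neutral
#' 60:40, emotional 80:20, emotional 60:40), each holding five 10-draw series
#' (jar A's ratio, jar B's ratio, 100:0, 0:100 and 50:50). Within-series draw
#' orders are generated pseudo-randomly from `seed` and stored verbatim, so a
#' task file is fully order-explicit and reproducible. The emotional blocks
#' are position-by-position images of the neutral ones under the fixed symbol
#' map (red -> happy, green -> angry).
#'
#' @param seed Integer seed controlling the within-series draw orders.
#' @param series_map Optional override of [canonical_series_map()]; must
#'   assign the same multiset of compositions to ids 1-7.
#' @return A `beads_task` object: list with `version`, `seed`, `series_map`
#'   and `blocks` (each block a list with `jar_ratio`, `content`,
#'   `p_dominant` and `series`).
#' @examples
#' task <- build_canonical_task(seed = 1)
#' length(task$blocks)                # 4
#' task_trials(task)[1:3, ]
#' @export
build_canonical_task <- function(seed = 1L, series_map = canonical_series_map()) {
  comps <- .check_series_map(series_map)
  seed <- as.integer(seed)
  blocks <- .with_seed(derive_seed(seed, "task-design"), {
    out <- list()
    for (jr in .JAR_RATIOS) {        # generate neutral blocks first, then map
      ids <- .block_series_ids(jr)
      sym <- .SYMBOLS$neutral
      series <- lapply(ids, function(id) {
        cmp <- comps[[as.character(id)]]
        pool <- rep(c(sym["A"], sym["B"]), cmp)
        draws <- unname(sample(pool))
        .make_series(id, cmp, "neutral", jr, draws)
      })
      out[[paste("neutral", jr)]] <- list(jar_ratio = jr, content = "neutral",
                                          p_dominant = .ratio_p(jr), series = series)
    }
    out
  })
  for (jr in .JAR_RATIOS) {
    neutral <- blocks[[paste("neutral", jr)]]
    series <- lapply(neutral$series, map_to_emotional)
    blocks[[paste("emotional", jr)]] <- list(jar_ratio = jr, content = "emotional",
                                             p_dominant = .ratio_p(jr), series = series)
  }
  # presentation order: neutral 80:20, neutral 60:40, emotional 80:20, emotional 60:40
  order_names <- c("neutral 80:20", "neutral 60:40", "emotional 80:20", "emotional 60:40")
  structure(list(
    version = "canonical-1",
    seed = seed,
    series_map = lapply(comps, as.integer),
    blocks = unname(blocks[order_names])
  ), class = "beads_task")
}

#' Map a neutral series to its emotional twin
#'
#' Applies the fixed symbol map (red -> happy, green -> angry) position by
#' position; series id, declared ratio and jar-ratio condition are preserved.
#'
#' @param series A neutral `series_spec`.
#' @return The emotional `series_spec`.
#' @export
map_to_emotional <- function(series) {
  if (!inherits(series, "series_spec")) stop("`series` must be a series_spec", call. = FALSE)
  if (series$content != "neutral") {
    stop("`series` already has emotional content; the map applies to neutral series",
         call. = FALSE)
  }
  out <- series
  out$content <- "emotional"
  out$draws <- unname(.SYMBOL_MAP[series$draws])
  out
}

#' Validate a task against the design invariants
#'
#' Checks every structural rule of the canonical design and returns the list
#' of violations; validation never raises.
#'
#' @param task A `beads_task`.
#' @return A data frame with columns `block`, `series_id`, `rule`, `detail`;
#'   zero rows when the task is valid.
#' @export
validate_task <- function(task) {
  v <- list()
  add <- function(block, series_id, rule, detail) {
    v[[length(v) + 1L]] <<- data.frame(block = block, series_id = series_id,
                                       rule = rule, detail = detail,
                                       stringsAsFactors = FALSE)
  }
  if (!is.list(task) || is.null(task$blocks)) {
    add(NA_character_, NA_integer_, "structure", "task has no blocks")
    return(do.call(rbind, v))
  }
  for (bi in seq_along(task$blocks)) {
    blk <- task$blocks[[bi]]
    bname <- paste(blk$content, blk$jar_ratio)
    sym <- .SYMBOLS[[blk$content]]
    if (length(blk$series) != 5L) {
      add(bname, NA_integer_, "block-size",
          sprintf("block has %d series, expected 5", length(blk$series)))
    }
    declared <- character(0)
    for (s in blk$series) {
      declared <- c(declared, paste(s$declared_ratio, collapse = ":"))
      if (length(s$draws) != 10L) {
        add(bname, s$series_id, "series-length",
            sprintf("series has %d draws, expected 10", length(s$draws)))
        next
      }
      counts <- c(sum(s$draws == sym["A"]), sum(s$draws == sym["B"]))
      if (!all(s$draws %in% sym)) {
        add(bname, s$series_id, "alphabet",
            paste("unknown symbols:", paste(setdiff(s$draws, sym), collapse = ", ")))
      } else if (!identical(as.integer(counts), as.integer(s$declared_ratio))) {
        add(bname, s$series_id, "declared-ratio",
            sprintf("draw counts %s do not match declared %s",
                    paste(counts, collapse = ":"),
                    paste(s$declared_ratio, collapse = ":")))
      }
    }
    p10 <- round(.ratio_p(blk$jar_ratio) * 10)
    wanted <- c(paste(p10, 10 - p10, sep = ":"), paste(10 - p10, p10, sep = ":"),
                "10:0", "0:10", "5:5")
    if (length(blk$series) == 5L && !setequal(declared, wanted)) {
      add(bname, NA_integer_, "composition-set",
          sprintf("block compositions {%s}, expected {%s}",
                  paste(sort(declared), collapse = ", "),
                  paste(sort(wanted), collapse = ", ")))
    }
  }
  # emotional blocks must be symbol-mapped images of their neutral twins
  key <- vapply(task$blocks, function(b) paste(b$content, b$jar_ratio), "")
  for (jr in .JAR_RATIOS) {
    ni <- match(paste("neutral", jr), key)
    ei <- match(paste("emotional", jr), key)
    if (is.na(ni) || is.na(ei)) next
    nb <- task$blocks[[ni]]$series
    eb <- task$blocks[[ei]]$series
    if (length(nb) != length(eb)) next
    for (k in seq_along(nb)) {
      mapped <- unname(.SYMBOL_MAP[nb[[k]]$draws])
      if (!identical(mapped, eb[[k]]$draws)) {
        add(paste("emotional", jr), eb[[k]]$series_id, "identical-sequences",
            "emotional draws are not the symbol-mapped image of the neutral twin")
      }
    }
  }
  if (length(v) == 0L) {
    return(data.frame(block = character(0), series_id = integer(0),
                      rule = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Long-format trial table of a task
#'
#' @param task A `beads_task`.
#' @return Data frame with one row per trial: `jar_ratio`, `content`,
#'   `series_id`, `position`, `symbol`, plus `is_b` (logical, symbol is the
#'   jar-B-dominant one).
#' @export
task_trials <- function(task) {
  rows <- lapply(task$blocks, function(blk) {
    sym <- .SYMBOLS[[blk$content]]
    do.call(rbind, lapply(blk$series, function(s) {
      data.frame(jar_ratio = blk$jar_ratio, content = blk$content,
                 series_id = s$series_id, position = seq_len(10L),
                 symbol = s$draws, is_b = s$draws == sym["B"],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a task file
#'
#' Tasks are serialized as YAML with blocks, series and verbatim draw lists,
#' plus the generating seed and map version, so serialize -> parse -> serialize
#' is byte-identical.
#'
#' @param task A `beads_task`.
#' @param path File path.
#' @return `read_task` returns the `beads_task`; `write_task` returns `path`
#'   invisibly.
#' @export
write_task <- function(task, path) {
  obj <- list(version = task$version, seed = task$seed,
              series_map = task$series_map,
              blocks = lapply(task$blocks, function(blk) {
                list(jar_ratio = blk$jar_ratio, content = blk$content,
                     p_dominant = blk$p_dominant,
                     series = lapply(blk$series, function(s) {
                       list(series_id = s$series_id,
                            declared_ratio = s$declared_ratio,
                            content = s$content,
                            jar_ratio_condition = s$jar_ratio_condition,
                            draws = s$draws)
                     }))
              }))
  yaml::write_yaml(obj, path, precision = 12L)
  invisible(path)
}

#' @rdname write_task
#' @export
read_task <- function(path) {
  obj <- yaml::read_yaml(path)
  blocks <- lapply(obj$blocks, function(blk) {
    list(jar_ratio = blk$jar_ratio, content = blk$content,
         p_dominant = blk$p_dominant,
         series = lapply(blk$series, function(s) {
           .make_series(s$series_id, s$declared_ratio, s$content,
                        s$jar_ratio_condition, unlist(s$draws))
         }))
  })
  structure(list(version = obj$version, seed = as.integer(obj$seed),
                 series_map = lapply(obj$series_map, as.integer),
                 blocks = blocks),
            class = "beads_task")
}

#' @export
print.beads_task <- function(x, ...) {
  cat(sprintf("beads_task (%s, seed %d): %d blocks x 5 series x 10 draws\n",
              x$version, x$seed, length(x$blocks)))
  for (blk in x$blocks) {
    ids <- vapply(blk$series, function(s) s$series_id, 0L)
    cat(sprintf("  %-9s %-5s series %s\n", blk$content, blk$jar_ratio,
                paste(ids, collapse = ", ")))
  }
  invisible(x)
}
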