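#' Plan a duplicate-detection run as a hypothesis test
#'
#' Duplicate detection is a classical hypothesis test: the null hypothesis
#' states that all `n_files` files in the warehouse satisfy the
#' delta-variability condition.  Fixing the significance level (the designed
#' false-alarm probability, conventionally 0.05) and solving for the sample
#' count via [required_sample_size()] yields a fingerprint configuration
#' under which any digest collision is evidence rejecting the null — the
#' colliding files are identical or highly similar and deserve inspection.
#'
#' @param n_files Number of files that will be scanned (at least 2).
#' @param delta Postulated variability of the collection (0.9 is reasonable
#'   for compressed files, 0.2 a general-purpose safe choice).
#' @param significance Designed false-alarm probability (default 0.05).
#' @param ... Further arguments passed to [fingerprint_config()] (e.g.
#'   `key`, `block_size`).
#' @return A [fingerprint_config()] with the planned sample count and
#'   `include_size = TRUE`.
#' @export
#' @examples
#' plan_test(59892, delta = 0.9)$samples  # 11
plan_test <- function(n_files, delta = 0.9, significance = 0.05, ...) {
  fingerprint_config(
    samples = required_sample_size(significance, n_files, delta),
    include_size = TRUE, ...)
}

files_identical <- function(a, b) {
  rep <- pairwise_delta(a, b)
  !rep$undefined && rep$size_a == rep$size_b && rep$delta == 0 ||
    rep$undefined && rep$size_a == 0 && rep$size_b == 0
}

#' Find duplicate (or equivalent) files by fingerprint collision
#'
#' Fingerprints every file once under one configuration and groups files by
#' digest.  Without confirmation a group contains files that are identical
#' *or* highly similar (a rejection of the delta-variability null); with
#' `confirm = TRUE` every group is verified by full-content comparison and
#' split into classes of byte-identical files.
#'
#' @param files Character vector (length >= 2) of paths/URLs.
#' @param config A [fingerprint_config()]; default: [plan_test()] for
#'   `length(files)` files at delta 0.9 and significance 0.05.
#' @param confirm Verify each group by full-content comparison?
#' @return A `pfff_dedup` object: `groups` (each with `members`,
#'   `fingerprint`, `total_bytes`, `redundant_bytes`, `confirmed`),
#'   `summary` (counts and total redundant bytes), `config`, and `failed`
#'   (inputs that could not be read — reported, never fatal).
#' @export
#' @examples
#' d <- tempfile(); dir.create(d)
#' for (i in 1:3) writeBin(as.raw(sample(0:255, 4096, TRUE)),
#'                         file.path(d, paste0("f", i)))
#' file.copy(file.path(d, "f1"), file.path(d, "copy"))
#' find_duplicates(list.files(d, full.names = TRUE))
find_duplicates <- function(files, config = NULL, confirm = FALSE) {
  stopifnot("need at least 2 files" = length(files) >= 2)
  if (is.null(config)) config <- plan_test(length(files))
  stopifnot(inherits(config, "pfff_config"))
  digests <- character(length(files))
  sizes <- numeric(length(files))
  ok <- logical(length(files))
  for (i in seq_along(files)) {
    fp <- tryCatch(pfff_fingerprint(files[i], config), error = identity)
    if (inherits(fp, "error")) {
      warning("skipping '", files[i], "': ", conditionMessage(fp),
              call. = FALSE)
    } else {
      digests[i] <- fp$digest; sizes[i] <- fp$size; ok[i] <- TRUE
    }
  }
  groups <- list()
  for (dg in unique(digests[ok])) {
    members <- which(ok & digests == dg)
    if (length(members) < 2) next
    classes <- if (confirm) {
      cls <- list()
      for (m in members) {
        placed <- FALSE
        for (ci in seq_along(cls)) {
          if (files_identical(files[m], files[cls[[ci]][1]])) {
            cls[[ci]] <- c(cls[[ci]], m); placed <- TRUE; break
          }
        }
        if (!placed) cls[[length(cls) + 1L]] <- m
      }
      Filter(function(x) length(x) >= 2, cls)
    } else list(members)
    for (members in classes) {
      total <- sum(sizes[members])
      groups[[length(groups) + 1L]] <- list(
        members = files[members], fingerprint = dg, total_bytes = total,
        redundant_bytes = total - sizes[members[1]], confirmed = confirm)
    }
  }
  groups <- groups[order(vapply(groups, function(g) -g$redundant_bytes, 0))]
  structure(
    list(groups = groups,
         summary = data.frame(
           n_files = length(files), n_hashed = sum(ok),
           n_groups = length(groups),
           redundant_bytes = sum(vapply(groups,
                                        function(g) g$redundant_bytes, 0))),
         config = config, failed = files[!ok]),
    class = "pfff_dedup")
}

#' @export
print.pfff_dedup <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d group(s) among %d hashed file(s); %.0f redundant bytes\n",
              s$n_groups, s$n_hashed, s$redundant_bytes))
  cat("config: ", config_string(x$config), "\n", sep = "")
  for (g in x$groups) {
    cat(sprintf("%s  n=%d  redundant=%.0f%s\n", g$fingerprint,
                length(g$members), g$redundant_bytes,
                if (g$confirmed) "  [confirmed identical]" else ""))
    for (m in g$members) cat("    ", m, "\n", sep = "")
  }
  if (length(x$failed))
    cat("unreadable (excluded):\n",
        paste0("    ", x$failed, "\n", collapse = ""), sep = "")
  invisible(x)
}

#' Write a duplicate-group report
#'
#' @param dedup A `pfff_dedup` object from [find_duplicates()].
#' @param path Output path (or `""` for stdout).
#' @param format `"text"` (one group per stanza) or `"json"` (JSON lines,
#'   one group object per line).
#' @return `path`, invisibly.
#' @export
write_duplicate_report <- function(dedup, path = "",
                                   format = c("text", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(dedup, "pfff_dedup"))
  if (format == "text") {
    if (path == "") print(dedup)
    else {
      con <- file(path, "w"); on.exit(close(con))
      sink(con); print(dedup); sink()
    }
  } else {
    lines <- vapply(dedup$groups, function(g)
      jsonlite::toJSON(g, auto_unbox = TRUE), "")
    if (path == "") cat(lines, sep = "\n")
    else writeLines(lines, path)
  }
  invisible(path)
}
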