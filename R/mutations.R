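# Each operator applies exactly one named defect to a valid tree, in place,
# and returns a record naming the issue code the validator must now emit.
# Operators are deliberately minimal: the diff touches exactly one file (or
# one filename).

first_artifact <- function(tree, ...) {
  hits <- query(tree, ...)
  if (!nrow(hits)) stop("no matching artifact in this tree", call. = FALSE)
  hits[1L, , drop = FALSE]
}

first_raw <- function(tree, task = NULL) {
  a <- tree$artifacts
  keep <- a$suffix == "meg" &
    (a$is_directory_payload | is.na(a$extension) | a$extension != "json")
  if (!is.null(task)) keep <- keep & !is.na(a$task) & a$task == task
  hits <- a[keep, , drop = FALSE]
  if (!nrow(hits)) stop("no matching raw recording", call. = FALSE)
  hits[1L, , drop = FALSE]
}

edit_json <- function(root, rel, fn) {
  p <- file.path(root, rel)
  doc <- jsonlite::fromJSON(p, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  doc <- fn(doc)
  json <- jsonlite::toJSON(doc, pretty = 4, auto_unbox = TRUE, digits = NA,
                           null = "null")
  con <- file(p, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
}

edit_lines <- function(root, rel, fn) {
  p <- file.path(root, rel)
  lines <- readLines(p, warn = FALSE)
  writeLines(fn(lines), p)
}

mutation_table <- function() {
  list(
    `break-entity-order` = list(
      code = "MEG-E001",
      description = "swap task/run entity order in a channels filename",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "channels")
        nm <- basename(tgt$relative_path)
        bad <- sub("task-([A-Za-z0-9]+)_run-([0-9]+)", "run-\\2_task-\\1",
                   nm)
        stopifnot(bad != nm)
        to <- file.path(dirname(file.path(root, tgt$relative_path)), bad)
        file.rename(file.path(root, tgt$relative_path), to)
        file.path(dirname(tgt$relative_path), bad)
      }),
    `bad-label-chars` = list(
      code = "MEG-E001",
      description = "inject a hyphen into a task label in an events filename",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "events")
        nm <- basename(tgt$relative_path)
        bad <- sub("task-([A-Za-z0-9])([A-Za-z0-9]+)_", "task-\\1-\\2_", nm)
        stopifnot(bad != nm)
        to <- file.path(dirname(file.path(root, tgt$relative_path)), bad)
        file.rename(file.path(root, tgt$relative_path), to)
        file.path(dirname(tgt$relative_path), bad)
      }),
    `delete-dataset-description` = list(
      code = "MEG-E002",
      description = "remove dataset_description.json",
      fn = function(root, tree) {
        file.remove(file.path(root, "dataset_description.json"))
        "dataset_description.json"
      }),
    `blank-dataset-name` = list(
      code = "MEG-E003",
      description = "drop the Name field from the dataset description",
      fn = function(root, tree) {
        edit_json(root, "dataset_description.json",
                  function(d) { d$Name <- NULL; d })
        "dataset_description.json"
      }),
    `misplace-file` = list(
      code = "MEG-E004",
      description = "move a session coordsystem.json into the meg folder",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "coordsystem")
        from <- tgt$relative_path
        to <- file.path(path_dir(from), "meg", basename(from))
        file.rename(file.path(root, from), file.path(root, to))
        to
      }),
    `remove-meg-sidecar` = list(
      code = "MEG-E010",
      description = paste("delete the empty-room run's only sidecar (no",
                          "root-level noise sidecar exists)"),
      fn = function(root, tree) {
        tgt <- first_artifact(tree, task = "noise", suffix = "meg",
                              extension = "json")
        file.remove(file.path(root, tgt$relative_path))
        tgt$relative_path
      }),
    `drop-required-meg-key` = list(
      code = "MEG-E011",
      description = "drop DewarPosition from a run-level MEG sidecar",
      fn = function(root, tree) {
        raw <- first_raw(tree, task = task_names(1))
        rel <- sub("\\.[A-Za-z0-9.]+$", ".json", raw$relative_path)
        edit_json(root, rel, function(d) { d$DewarPosition <- NULL; d })
        rel
      }),
    `corrupt-json` = list(
      code = "MEG-E012",
      description = "truncate a coordsystem.json mid-token",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "coordsystem")
        edit_lines(root, tgt$relative_path,
                   function(l) substr(paste(l, collapse = "\n"), 1, 25))
        tgt$relative_path
      }),
    `stringify-boolean` = list(
      code = "MEG-E013",
      description = "turn DigitizedLandmarks into the string \"true\"",
      fn = function(root, tree) {
        raw <- first_raw(tree, task = task_names(1))
        rel <- sub("\\.[A-Za-z0-9.]+$", ".json", raw$relative_path)
        edit_json(root, rel,
                  function(d) { d$DigitizedLandmarks <- "true"; d })
        rel
      }),
    `remove-channels-file` = list(
      code = "MEG-W011",
      description = "delete one channels.tsv",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "channels")
        file.remove(file.path(root, tgt$relative_path))
        tgt$relative_path
      }),
    `ragged-tsv-row` = list(
      code = "MEG-E014",
      description = "append a stray cell to one channels.tsv row",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "channels")
        edit_lines(root, tgt$relative_path, function(l) {
          l[2] <- paste0(l[2], "\tstray")
          l
        })
        tgt$relative_path
      }),
    `duplicate-channel-name` = list(
      code = "MEG-E015",
      description = "give the second channel the first channel's name",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "channels")
        edit_lines(root, tgt$relative_path, function(l) {
          c1 <- strsplit(l[2], "\t", fixed = TRUE)[[1]]
          c2 <- strsplit(l[3], "\t", fixed = TRUE)[[1]]
          c2[1] <- c1[1]
          l[3] <- paste(c2, collapse = "\t")
          l
        })
        tgt$relative_path
      }),
    `add-conflicting-sidecar` = list(
      code = "MEG-E016",
      description = paste("add a root run-01 sidecar tying with the root",
                          "task sidecar at equal depth and specificity"),
      fn = function(root, tree) {
        write_json_sidecar(list(DewarPosition = "upright"),
                           file.path(root, "run-01_meg.json"),
                           schema = "meg", partial = TRUE)
        "run-01_meg.json"
      }),
    `remove-coordsystem` = list(
      code = "MEG-E020",
      description = "delete a session's coordsystem.json",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "coordsystem")
        file.remove(file.path(root, tgt$relative_path))
        tgt$relative_path
      }),
    `invalid-coordinate-system-token` = list(
      code = "MEG-E021",
      description = "set MEGCoordinateSystem to an unregistered token",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "coordsystem")
        edit_json(root, tgt$relative_path,
                  function(d) { d$MEGCoordinateSystem <- "MagnetLand"; d })
        tgt$relative_path
      }),
    `invalid-units` = list(
      code = "MEG-E022",
      description = "set MEGCoordinateUnits to furlong",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "coordsystem")
        edit_json(root, tgt$relative_path,
                  function(d) { d$MEGCoordinateUnits <- "furlong"; d })
        tgt$relative_path
      }),
    `collinear-fiducials` = list(
      code = "MEG-E023",
      description = "replace the anatomical landmarks with collinear points",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "coordsystem")
        edit_json(root, tgt$relative_path, function(d) {
          d$AnatomicalLandmarkCoordinates <-
            list(NAS = c(0, 0, 0), LPA = c(1, 0, 0), RPA = c(2, 0, 0))
          d
        })
        tgt$relative_path
      }),
    `scans-references-missing-file` = list(
      code = "MEG-E031",
      description = "append a scans.tsv row pointing at a ghost recording",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "scans")
        edit_lines(root, tgt$relative_path, function(l) {
          c(l, "meg/sub-99_task-ghost_run-99_meg.fif\tn/a")
        })
        tgt$relative_path
      }),
    `mismatch-channel-count` = list(
      code = "MEG-W030",
      description = "offset MEGChannelCount by +1 in a run sidecar",
      fn = function(root, tree) {
        raw <- first_raw(tree, task = task_names(1))
        rel <- sub("\\.[A-Za-z0-9.]+$", ".json", raw$relative_path)
        edit_json(root, rel, function(d) {
          d$MEGChannelCount <- d$MEGChannelCount + 1L
          d
        })
        rel
      }),
    `orphan-participant-row` = list(
      code = "MEG-W032",
      description = "append a participants.tsv row without a subject folder",
      fn = function(root, tree) {
        edit_lines(root, "participants.tsv", function(l) {
          ncol <- length(strsplit(l[1], "\t", fixed = TRUE)[[1]])
          c(l, paste(c("sub-zz", rep("n/a", ncol - 1)), collapse = "\t"))
        })
        "participants.tsv"
      }),
    `event-onset-past-duration` = list(
      code = "MEG-W033",
      description = "push one event onset beyond the recording duration",
      fn = function(root, tree) {
        tgt <- first_artifact(tree, suffix = "events")
        edit_lines(root, tgt$relative_path, function(l) {
          cells <- strsplit(l[length(l)], "\t", fixed = TRUE)[[1]]
          cells[1] <- "99999"
          l[length(l)] <- paste(cells, collapse = "\t")
          l
        })
        tgt$relative_path
      }),
    `break-emptyroom-link` = list(
      code = "MEG-W034",
      description = "point AssociatedEmptyRoom at a nonexistent path",
      fn = function(root, tree) {
        raw <- first_raw(tree, task = task_names(1))
        rel <- sub("\\.[A-Za-z0-9.]+$", ".json", raw$relative_path)
        edit_json(root, rel, function(d) {
          d$AssociatedEmptyRoom <- "sub-99/meg/sub-99_task-noise_meg.fif"
          d
        })
        rel
      }))
}

#' Registry of mutation operators
#'
#' One named, minimal defect per operator, together with the validator
#' issue code the mutated tree must now trigger. Every ERROR-severity code
#' in [issue_registry()] is killed by at least one operator.
#'
#' @return Data frame with columns `id`, `expected_code`, `description`.
#' @export
mutation_operators <- function() {
  tab <- mutation_table()
  data.frame(id = names(tab),
             expected_code = vapply(tab, `[[`, "", "code"),
             description = vapply(tab, `[[`, "", "description"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply one mutation operator to a dataset tree
#'
#' Mutates the tree at `root` in place (exactly one file changed, renamed,
#' added or removed) and returns a mutation record. An operator that finds
#' no applicable target (e.g. `remove-meg-sidecar` on a tree without an
#' empty-room run) refuses with an error.
#'
#' @param root Dataset root (a valid tree, e.g. from
#'   [generate_dataset()]).
#' @param operator Operator id; see [mutation_operators()].
#' @param seed Unused by the current deterministic operators; kept so that
#'   randomised operators stay seedable.
#' @return List with `operator`, `path` (the touched file),
#'   `expected_code`.
#' @export
mutate_dataset <- function(root, operator, seed = 1L) {
  tab <- mutation_table()
  op <- tab[[operator]]
  if (is.null(op)) stop("unknown mutation operator '", operator, "'",
                        call. = FALSE)
  tree <- scan_tree(root)
  path <- tryCatch(with_seed(seed, op$fn(root, tree)),
                   error = function(e) {
                     stop("operator '", operator, "' is not applicable: ",
                          conditionMessage(e), call. = FALSE)
                   })
  list(operator = operator, path = path, expected_code = op$code)
}
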