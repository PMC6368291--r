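#' Patient session
#'
#' A session gathers all data belonging to one patient under one directory:
#' named volumes, masks, trees, targets and routes. A session serializes to
#' disk ([save_session()]) and reloads losslessly ([load_session()]).
#'
#' @param patient_dir Directory for the patient's data (created if needed).
#' @return A `bronchoplan_session`.
#' @export
new_session <- function(patient_dir) {
  if (!dir.exists(patient_dir)) dir.create(patient_dir, recursive = TRUE)
  structure(list(patient_dir = patient_dir,
                 volumes = list(), masks = list(), trees = list(),
                 targets = empty_targets(), routes = list()),
            class = "bronchoplan_session")
}

empty_targets <- function() {
  tibble::tibble(name = character(), x = numeric(), y = numeric(),
                 z = numeric(), color = character(), created = character())
}

#' @export
print.bronchoplan_session <- function(x, ...) {
  cat("<bronchoplan_session> ", x$patient_dir, "\n",
      "  volumes: ", paste(names(x$volumes), collapse = ", "), "\n",
      "  masks:   ", paste(names(x$masks), collapse = ", "), "\n",
      "  trees:   ", paste(names(x$trees), collapse = ", "), "\n",
      "  targets: ", paste(x$targets$name, collapse = ", "), "\n",
      "  routes:  ", paste(names(x$routes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

session_put <- function(session, category, name, value) {
  session[[category]][[name]] <- value
  session
}

#' Manage pinpointed targets in a session
#'
#' CRUD operations on the session's named target points: `add`, `move`
#' (assign new coordinates — this also covers re-picking a target), `rename`,
#' `delete`, `recolor`. Adding a duplicate name or renaming onto an existing
#' name is a conflict; operating on a missing name is a lookup error.
#'
#' @param session A `bronchoplan_session`.
#' @param action One of `"add"`, `"move"`, `"rename"`, `"delete"`,
#'   `"recolor"`.
#' @param name Target name the action applies to.
#' @param position Length-3 mm position (`add`, `move`).
#' @param color Color string (`add`, `recolor`).
#' @param new_name Replacement name (`rename`).
#' @return The modified session.
#' @export
pinpoint <- function(session, action, name, position = NULL, color = "#FF0000",
                     new_name = NULL) {
  action <- match.arg(action, c("add", "move", "rename", "delete", "recolor"))
  tg <- session$targets
  exists_ <- name %in% tg$name
  if (action == "add") {
    if (exists_) {
      abort(paste0("target '", name, "' already exists."),
            class = "bronchoplan_conflict_error")
    }
    session$targets <- dplyr::bind_rows(
      tg, target(name, position, color = color,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
    return(session)
  }
  if (!exists_) {
    abort(paste0("no target named '", name, "'."),
          class = "bronchoplan_lookup_error")
  }
  i <- which(tg$name == name)
  if (action == "move") {
    position <- as.numeric(position)
    if (length(position) != 3L || any(!is.finite(position))) {
      abort("`position` must be 3 finite coordinates.",
            class = "bronchoplan_parameter_error")
    }
    tg$x[i] <- position[1]; tg$y[i] <- position[2]; tg$z[i] <- position[3]
  } else if (action == "rename") {
    if (is.null(new_name) || !nzchar(new_name)) {
      abort("`new_name` required.", class = "bronchoplan_parameter_error")
    }
    if (new_name %in% tg$name) {
      abort(paste0("target '", new_name, "' already exists."),
            class = "bronchoplan_conflict_error")
    }
    tg$name[i] <- new_name
  } else if (action == "delete") {
    tg <- tg[-i, ]
  } else if (action == "recolor") {
    tg$color[i] <- color
  }
  session$targets <- tg
  session
}

#' Save and load a session
#'
#' Volumes and masks are written as MetaImage (`MET_DOUBLE` / `MET_UCHAR`,
#' lossless), trees and routes as JSON, targets as JSON, plus an `index.json`
#' naming everything. Writers are deterministic, so save - load - save
#' produces identical files.
#'
#' @param session A `bronchoplan_session`.
#' @param patient_dir Directory holding a saved session.
#' @return `save_session()` returns the session invisibly; `load_session()`
#'   returns the reloaded session.
#' @export
save_session <- function(session) {
  dir <- session$patient_dir
  idx <- list(volumes = names(session$volumes), masks = names(session$masks),
              trees = names(session$trees), routes = names(session$routes))
  jsonlite::write_json(idx, file.path(dir, "index.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (nm in names(session$volumes)) {
    write_volume_mhd(session$volumes[[nm]],
                     file.path(dir, paste0("volume_", nm, ".mhd")))
  }
  for (nm in names(session$masks)) {
    write_volume_mhd(session$masks[[nm]],
                     file.path(dir, paste0("mask_", nm, ".mhd")))
  }
  for (nm in names(session$trees)) {
    write_tree_json(session$trees[[nm]],
                    file.path(dir, paste0("tree_", nm, ".json")))
  }
  for (nm in names(session$routes)) {
    write_route_json(session$routes[[nm]],
                     file.path(dir, paste0("route_", nm, ".json")))
  }
  write_targets_json(session$targets, file.path(dir, "targets.json"))
  invisible(session)
}

#' @rdname save_session
#' @export
load_session <- function(patient_dir) {
  idx <- jsonlite::read_json(file.path(patient_dir, "index.json"),
                             simplifyVector = TRUE)
  s <- new_session(patient_dir)
  for (nm in idx$volumes) {
    s$volumes[[nm]] <- read_volume_mhd(file.path(patient_dir,
                                                 paste0("volume_", nm, ".mhd")))
  }
  for (nm in idx$masks) {
    v <- read_volume_mhd(file.path(patient_dir, paste0("mask_", nm, ".mhd")))
    s$masks[[nm]] <- binary_mask(v$grid, v$data)
  }
  for (nm in idx$trees) {
    s$trees[[nm]] <- read_tree_json(file.path(patient_dir,
                                              paste0("tree_", nm, ".json")))
  }
  for (nm in idx$routes) {
    s$routes[[nm]] <- read_route_json(file.path(patient_dir,
                                                paste0("route_", nm, ".json")))
  }
  tpath <- file.path(patient_dir, "targets.json")
  if (file.exists(tpath)) {
    tg <- read_targets_json(tpath)
    s$targets <- if (nrow(tg)) tg else empty_targets()
  }
  s
}
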