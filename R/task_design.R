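#' Object sets and randomized presentation schedules
#'
#' The discrimination tasks present objects that vary in size class and/or
#' compliance class. Each object carries two physical surrogates used by the
#' grasp simulator: the hand-closure angle at which the fingertips first touch
#' it (`contact_aperture`, degrees; larger objects are contacted at larger
#' aperture) and a linear contact stiffness (`stiffness`, N per degree of
#' closure beyond contact; stiffer = less compliant).
#'
#' @name task_design
NULL

SIZE_LEVELS <- c("XS", "S", "M", "L")
COMPLIANCE_LEVELS <- c("soft", "medium", "hard")
SHAPES <- c("sphere", "cylinder", "cube")

# Default physical surrogates. Only their ordering matters to the analysis;
# values are documented choices (see the methods vignette).
DEFAULT_CONTACT_APERTURE <- c(XS = 20, S = 30, M = 45, L = 60)
# S2 cylinders: graspable diameters in 5-degree aperture steps
CYLINDER_CONTACT_APERTURE <- c(XS = 35, S = 40, M = 45, L = 50)
DEFAULT_STIFFNESS <- c(soft = 0.05, medium = 0.15, hard = 0.45)

#' Build an object set
#'
#' Constructs the full factorial crossing of the requested size and compliance
#' classes (singleton-property sets when one property is held fixed), either
#' from a named preset or from explicit class lists plus physical surrogates.
#'
#' @param preset Optional preset name; see [list_presets()].
#' @param shape One of `"sphere"`, `"cylinder"`, `"cube"`.
#' @param sizes Character vector of size classes (subset of XS, S, M, L).
#' @param compliances Character vector of compliance classes
#'   (subset of soft, medium, hard).
#' @param contact_apertures Named numeric vector (deg) giving the contact
#'   aperture per size class. Must be strictly increasing with size class.
#' @param stiffnesses Named numeric vector (N/deg) per compliance class.
#'   Must be strictly increasing soft < medium < hard, all > 0.
#' @return A data.frame of class `object_set` with one row per object:
#'   `shape`, `size_class`, `compliance_class`, `contact_aperture`,
#'   `stiffness`.
#' @examples
#' nrow(build_object_set(preset = "S1-virtual-size")) # 9 spheres
#' @export
build_object_set <- function(preset = NULL,
                             shape = "sphere",
                             sizes = c("S", "M", "L"),
                             compliances = c("soft", "medium", "hard"),
                             contact_apertures = DEFAULT_CONTACT_APERTURE,
                             stiffnesses = DEFAULT_STIFFNESS) {
  if (!is.null(preset)) {
    return(preset_config(preset)$object_set)
  }
  shape <- match.arg(shape, SHAPES)
  if (length(sizes) < 1 || length(compliances) < 1) {
    stop("at least one size class and one compliance class are required")
  }
  sizes <- match.arg(sizes, SIZE_LEVELS, several.ok = TRUE)
  compliances <- match.arg(compliances, COMPLIANCE_LEVELS, several.ok = TRUE)

  ca <- contact_apertures[sizes]
  st <- stiffnesses[compliances]
  if (anyNA(ca)) stop("contact_apertures must name every requested size class")
  if (anyNA(st)) stop("stiffnesses must name every requested compliance class")
  # invariants: contact aperture strictly increasing with size class,
  # stiffness strictly increasing with compliance class and positive
  ord <- order(match(sizes, SIZE_LEVELS))
  if (length(ca) > 1 && any(diff(ca[ord]) <= 0)) {
    stop("invariant violation: contact_aperture must be strictly increasing ",
         "with size_class (larger objects are contacted at larger aperture)")
  }
  ordc <- order(match(compliances, COMPLIANCE_LEVELS))
  if (any(st <= 0)) stop("invariant violation: stiffness must be > 0")
  if (length(st) > 1 && any(diff(st[ordc]) <= 0)) {
    stop("invariant violation: stiffness must be strictly increasing ",
         "soft < medium < hard")
  }

  grid <- expand.grid(size_class = sizes, compliance_class = compliances,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    shape = shape,
    size_class = factor(grid$size_class, levels = SIZE_LEVELS),
    compliance_class = factor(grid$compliance_class,
                              levels = COMPLIANCE_LEVELS),
    contact_aperture = unname(ca[grid$size_class]),
    stiffness = unname(st[grid$compliance_class]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$compliance_class, out$size_class), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("object_set", "data.frame")
  out
}

#' List the built-in task presets
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  c("S1-virtual-size", "S1-virtual-compliance", "S1-physical-size",
    "S2-virtual-compliance", "S2-physical-size", "S2-physical-compliance")
}

#' Retrieve the full configuration of a built-in preset
#'
#' Each preset bundles the object set, per-object repetition counts, the
#' control scheme and encoding scheme used in that session type, the
#' exploration timeout, and the property the subject was asked to report.
#'
#' @param name Preset name; see [list_presets()].
#' @return A list with elements `name`, `object_set`, `repetitions`,
#'   `control_scheme`, `encoding_scheme`, `timeout_s`, `queried_property`,
#'   `n_trials`.
#' @export
preset_config <- function(name) {
  name <- match.arg(name, list_presets())
  cfg <- switch(name,
    "S1-virtual-size" = list(
      object_set = build_object_set(shape = "sphere"),
      repetitions = 8, control_scheme = "glove_proportional",
      encoding_scheme = "exponential", timeout_s = 10,
      queried_property = "size"),
    "S1-virtual-compliance" = list(
      object_set = build_object_set(shape = "sphere"),
      repetitions = 10, control_scheme = "glove_proportional",
      encoding_scheme = "exponential", timeout_s = 10,
      queried_property = "compliance"),
    "S1-physical-size" = list(
      # four foam-rubber cubes, one compliance level
      object_set = build_object_set(shape = "cube",
                                    sizes = c("XS", "S", "M", "L"),
                                    compliances = "medium"),
      repetitions = c(XS = 9, S = 18, M = 12, L = 16),
      control_scheme = "glove_proportional",
      encoding_scheme = "linear", timeout_s = 10,
      queried_property = "size"),
    "S2-virtual-compliance" = list(
      # three compliances, all large cylinders
      object_set = build_object_set(shape = "cylinder", sizes = "L",
                                    contact_apertures = CYLINDER_CONTACT_APERTURE),
      repetitions = 25, control_scheme = "emg_threshold_velocity",
      encoding_scheme = "linear", timeout_s = 10,
      queried_property = "compliance"),
    "S2-physical-size" = list(
      # three sizes, all hard cylinders
      object_set = build_object_set(shape = "cylinder",
                                    sizes = c("S", "M", "L"),
                                    compliances = "hard",
                                    contact_apertures = CYLINDER_CONTACT_APERTURE),
      repetitions = 10, control_scheme = "emg_threshold_velocity",
      encoding_scheme = "linear", timeout_s = 20,
      queried_property = "size"),
    "S2-physical-compliance" = list(
      # three compliances, all medium cylinders
      object_set = build_object_set(shape = "cylinder", sizes = "M",
                                    contact_apertures = CYLINDER_CONTACT_APERTURE),
      repetitions = 20, control_scheme = "emg_threshold_velocity",
      encoding_scheme = "linear", timeout_s = 20,
      queried_property = "compliance")
  )
  cfg$name <- name
  reps <- cfg$repetitions
  cfg$n_trials <- if (length(reps) == 1) reps * nrow(cfg$object_set) else
    sum(reps[as.character(cfg$object_set$size_class)])
  cfg
}

#' Build a randomized session schedule
#'
#' Expands the object set to the configured per-object repetition counts and
#' applies a single uniform shuffle (or block randomization when
#' `blocked = TRUE`: objects shuffled within successive blocks of one
#' presentation each).
#'
#' @param object_set An `object_set` from [build_object_set()].
#' @param repetitions Single count applied to every object, or a vector of
#'   per-object counts (length `nrow(object_set)`, or named by size class when
#'   only size varies). All counts must be >= 0.
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param timeout Exploration timeout in seconds.
#' @param queried_property `"size"` or `"compliance"` (stored per trial;
#'   both properties may vary while only one is queried).
#' @param blocked If `TRUE`, randomize within blocks containing one
#'   presentation of each object (only valid for uniform repetitions).
#' @return A data.frame of class `session_schedule` with columns
#'   `trial_index`, `shape`, `size_class`, `compliance_class`,
#'   `contact_aperture`, `stiffness`, `queried_property`, `timeout_s`, and
#'   attributes `seed`, `task_label`.
#' @export
make_schedule <- function(object_set, repetitions, seed = 1L, timeout = 10,
                          queried_property = c("size", "compliance"),
                          blocked = FALSE) {
  stopifnot(inherits(object_set, "object_set"))
  queried_property <- match.arg(queried_property)
  n_obj <- nrow(object_set)
  if (length(repetitions) == 1) {
    reps <- rep(repetitions, n_obj)
  } else if (!is.null(names(repetitions))) {
    reps <- unname(repetitions[as.character(object_set$size_class)])
    if (anyNA(reps)) stop("named repetitions must cover every size class")
  } else {
    if (length(repetitions) != n_obj) {
      stop("repetitions must be length 1 or nrow(object_set)")
    }
    reps <- repetitions
  }
  if (any(reps < 0) || any(reps != round(reps))) {
    stop("repetition counts must be non-negative integers")
  }

  idx <- rep(seq_len(n_obj), times = reps)
  perm <- with_seed(seed, {
    if (blocked) {
      if (length(unique(reps)) != 1) {
        stop("blocked randomization requires uniform repetition counts")
      }
      # one presentation of every object per block, shuffled within block
      unlist(lapply(seq_len(reps[1]), function(b) sample(seq_len(n_obj))))
    } else if (length(idx) > 0) {
      sample(idx)
    } else {
      integer(0)
    }
  })
  sched <- object_set[perm, , drop = FALSE]
  rownames(sched) <- NULL
  sched <- cbind(trial_index = seq_len(nrow(sched)), sched)
  sched$queried_property <- if (nrow(sched)) queried_property else character(0)
  sched$timeout_s <- if (nrow(sched)) timeout else numeric(0)
  attr(sched, "seed") <- as.integer(seed)
  attr(sched, "task_label") <- paste0(queried_property, "_discrimination")
  class(sched) <- c("session_schedule", "data.frame")
  sched
}

#' Build the schedule for a built-in preset
#'
#' @param name Preset name; see [list_presets()].
#' @param seed Integer seed for the shuffle.
#' @param blocked Passed to [make_schedule()].
#' @return A `session_schedule`.
#' @export
preset_schedule <- function(name, seed = 1L, blocked = FALSE) {
  cfg <- preset_config(name)
  make_schedule(cfg$object_set, cfg$repetitions, seed = seed,
                timeout = cfg$timeout_s,
                queried_property = cfg$queried_property, blocked = blocked)
}

#' Write a schedule to CSV
#'
#' RFC-4180 CSV with header row:
#' trial_index, shape, size_class, compliance_class, contact_aperture,
#' stiffness, queried_property, timeout_s, seed.
#'
#' @param schedule A `session_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  df <- as.data.frame(schedule)
  df$seed <- attr(schedule, "seed")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a schedule written by [write_schedule_csv()]
#'
#' @param path CSV path.
#' @return A `session_schedule`.
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  seed <- if ("seed" %in% names(df)) df$seed[1] else NA_integer_
  df$seed <- NULL
  df$size_class <- factor(df$size_class, levels = SIZE_LEVELS)
  df$compliance_class <- factor(df$compliance_class,
                                levels = COMPLIANCE_LEVELS)
  attr(df, "seed") <- as.integer(seed)
  attr(df, "task_label") <- paste0(df$queried_property[1], "_discrimination")
  class(df) <- c("session_schedule", "data.frame")
  df
}
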