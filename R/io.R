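#' @title File formats, run configuration and the pipeline driver
#' @description
#' PDB output of duplex models (REMARK lines carry pairing and unit
#' metadata so models round-trip losslessly), XYZ trajectory I/O with
#' step/temperature/D/lambda annotations in the frame comments, CSV
#' trace writers, a YAML run configuration, and the pipeline driver
#' chaining build, zip-up, annealing, thermodynamic integration and the
#' structural analyses into one reproducible run directory.
#' @name io_cli
NULL

.pdb_resname <- function(base) {
  c(A = "DA", T = "DT", G = "DG", C = "DC", iG = "IGU", eA = "EAD")[base]
}

#' Write a duplex model to PDB
#'
#' Strands become chains A and B; Hg and counter ions are HETATM records
#' in chain X.  `REMARK 250 DYNDIST` lines record the orientation, helix
#' parameters, per-unit metadata and the pairing table, allowing
#' [read_pdb_duplex()] to reconstruct the full model.
#'
#' @param duplex a `duplex_model`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_pdb_duplex <- function(duplex, file) {
  u <- duplex$units
  a <- duplex$atoms
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("REMARK 250 DYNDIST ORIENTATION %s", duplex$orientation)
  wl("REMARK 250 DYNDIST HELIX RISE %.6f TWIST %.6f", duplex$rise,
     duplex$twist)
  for (r in seq_len(nrow(u))) {
    wl("REMARK 250 DYNDIST UNIT %d %s %d %d %d %d %d",
       u$unit_id[r], u$base_code[r], u$strand[r], u$pos5to3[r],
       u$resid[r], u$level[r], u$base_charge[r])
  }
  p <- duplex$pairing
  for (r in seq_len(nrow(p))) {
    wl("REMARK 250 DYNDIST PAIR %d %d %d %s", p$level[r],
       p$strand1_pos[r], p$strand2_pos[r], p$pair_class[r])
  }
  for (r in seq_len(nrow(a))) {
    if (!is.na(a$unit_id[r])) {
      ur <- u[u$unit_id == a$unit_id[r], ]
      chain <- c("A", "B")[ur$strand]
      resno <- ur$resid
      resname <- .pdb_resname(ur$base_code)
      rec <- "ATOM  "
    } else {
      chain <- "X"
      resname <- switch(a$element[r], Hg = "HG", Na = "NA", Cl = "CL",
                        "UNK")
      resno <- 900L + r
      rec <- "HETATM"
    }
    name <- a$site[r]
    name <- gsub("[+-]", "", name)
    name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else
      substr(name, 1L, 4L)
    wl("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
       rec, a$serial[r], name4, resname, chain, resno,
       a$x[r], a$y[r], a$z[r], 1, 0, toupper(a$element[r]))
  }
  wl("END")
  invisible(file)
}

#' Read a duplex model written by [write_pdb_duplex()]
#'
#' Coordinates are parsed with `bio3d::read.pdb()` when available (a
#' fixed-column fallback parser is used otherwise); the `DYNDIST`
#' REMARK lines restore units, pairing, orientation and helix
#' parameters.  Charges are reconstructed from site identity
#' (phosphates -1, Na+ +1, Cl- -1, Hg +2, N3 of a deprotonated modified
#' thymine -1).
#'
#' @param file PDB path.
#' @return a `duplex_model`.
#' @export
read_pdb_duplex <- function(file) {
  lines <- readLines(file)
  atrec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(atrec & nchar(lines) < 54L)
  if (length(bad)) {
    stop("malformed (truncated) PDB record at line ",
         paste(bad, collapse = ", "))
  }
  rm_unit <- grep("^REMARK 250 DYNDIST UNIT ", lines, value = TRUE)
  rm_pair <- grep("^REMARK 250 DYNDIST PAIR ", lines, value = TRUE)
  rm_or <- grep("^REMARK 250 DYNDIST ORIENTATION ", lines, value = TRUE)
  rm_hx <- grep("^REMARK 250 DYNDIST HELIX ", lines, value = TRUE)
  if (!length(rm_unit) || !length(rm_or)) {
    stop("file lacks DYNDIST remarks; not a duplex-model PDB")
  }
  units <- do.call(rbind, lapply(rm_unit, function(l) {
    f <- strsplit(trimws(sub("^REMARK 250 DYNDIST UNIT ", "", l)),
                  "\\s+")[[1]]
    data.frame(unit_id = as.integer(f[1]), base_code = f[2],
               strand = as.integer(f[3]), pos5to3 = as.integer(f[4]),
               resid = as.integer(f[5]), level = as.integer(f[6]),
               base_charge = as.integer(f[7]))
  }))
  pairing <- do.call(rbind, lapply(rm_pair, function(l) {
    f <- strsplit(trimws(sub("^REMARK 250 DYNDIST PAIR ", "", l)),
                  "\\s+")[[1]]
    data.frame(level = as.integer(f[1]), strand1_pos = as.integer(f[2]),
               strand2_pos = as.integer(f[3]), pair_class = f[4])
  }))
  orientation <- trimws(sub("^REMARK 250 DYNDIST ORIENTATION ", "",
                            rm_or[1]))
  hx <- strsplit(trimws(sub("^REMARK 250 DYNDIST HELIX ", "",
                            rm_hx[1])), "\\s+")[[1]]
  rise <- as.numeric(hx[2]); twist <- as.numeric(hx[4])

  if (requireNamespace("bio3d", quietly = TRUE)) {
    pdb <- suppressWarnings(bio3d::read.pdb(file, verbose = FALSE))
    at <- pdb$atom
    adf <- data.frame(site = trimws(at$elety), chain = at$chain,
                      resno = at$resno, x = at$x, y = at$y, z = at$z,
                      element = {
                        e <- trimws(at$elesy)
                        substr(e, 2, nchar(e)) <-
                          tolower(substr(e, 2, nchar(e)))
                        e
                      })
  } else {
    rl <- lines[atrec]
    adf <- data.frame(
      site = trimws(substr(rl, 13, 16)), chain = trimws(substr(rl, 22, 22)),
      resno = as.integer(substr(rl, 23, 26)),
      x = as.numeric(substr(rl, 31, 38)),
      y = as.numeric(substr(rl, 39, 46)),
      z = as.numeric(substr(rl, 47, 54)),
      element = {
        e <- trimws(substr(rl, 77, 78))
        substr(e, 2, nchar(e)) <- tolower(substr(e, 2, nchar(e)))
        e
      })
  }
  n <- nrow(adf)
  unit_id <- rep(NA_integer_, n)
  site <- adf$site
  in_chain <- adf$chain %in% c("A", "B")
  unit_id[in_chain] <- units$unit_id[match(adf$resno[in_chain],
                                           units$resid)]
  ## het records: restore ion site labels
  het <- !in_chain
  site[het & adf$element == "Na"] <- "Na+"
  site[het & adf$element == "Cl"] <- "Cl-"
  charge <- rep(0, n)
  charge[site == "P"] <- -1
  charge[site == "Na+"] <- 1
  charge[site == "Cl-"] <- -1
  charge[adf$element == "Hg"] <- 2
  deprot <- units$unit_id[units$base_charge == -1L]
  charge[unit_id %in% deprot & site == "N3"] <- -1
  atoms <- data.frame(unit_id = unit_id, site = site,
                      element = adf$element, x = adf$x, y = adf$y,
                      z = adf$z, charge = charge)
  .new_duplex(units, atoms, pairing, orientation, rise, twist)
}

#' Write an XYZ trajectory
#'
#' Standard XYZ with one block per frame; the comment line carries
#' `step=`, `time=`, `T=`, `D=`, `lambda=` annotations when available.
#'
#' @param frames list of N x 3 position matrices (or a single matrix).
#' @param elements length-N element symbols.
#' @param file output path.
#' @param comments optional character vector (one per frame) or a trace
#'   data.frame from [run_nvt()] whose rows annotate the saved frames.
#' @return the file path, invisibly.
#' @export
write_xyz <- function(frames, elements, file, comments = NULL) {
  if (!is.list(frames)) frames <- list(frames)
  if (is.data.frame(comments)) {
    comments <- sprintf("step=%d time=%.3f T=%.2f D=%s lambda=%s",
                        comments$step, comments$time,
                        comments$temperature,
                        formatC(comments$D, digits = 6, format = "f"),
                        formatC(comments$lambda, digits = 6,
                                format = "f"))
  }
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    pos <- frames[[k]]
    writeLines(as.character(nrow(pos)), con)
    writeLines(if (!is.null(comments) && length(comments) >= k)
      comments[k] else sprintf("frame %d", k), con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", elements,
                       pos[, 1L], pos[, 2L], pos[, 3L]), con)
  }
  invisible(file)
}

#' Read an XYZ trajectory
#'
#' @param file XYZ path.
#' @return list with `elements`, `frames` (list of N x 3 matrices) and
#'   `comments` (one per frame).
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list(); comments <- character(0); elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      stop("malformed XYZ atom count at line ", i)
    }
    if (i + 1L + nat > length(lines)) {
      stop("truncated XYZ frame starting at line ", i)
    }
    comments <- c(comments, lines[i + 1L])
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    badrow <- which(lengths(parts) < 4L)
    if (length(badrow)) {
      stop("malformed XYZ coordinate record at line ", i + 1L + badrow[1L])
    }
    el <- vapply(parts, `[`, character(1), 1L)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3L, byrow = TRUE)
    if (anyNA(xyz)) stop("non-numeric coordinates in frame at line ", i)
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
  }
  list(elements = elements, frames = frames, comments = comments)
}

#' Write a trace or profile table to CSV
#'
#' @param x data.frame (an MD trace, TI window table, or
#'   `free_energy_profile` via its `as.data.frame` method).
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_csv_trace <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

## ---- run configuration --------------------------------------------------

#' Default run configuration
#'
#' @param seed master seed; each pipeline stage derives its own stream
#'   from it.
#' @param outdir output directory.
#' @param ... overrides merged into the default tree (named sublists
#'   `structure`, `md`, `ti`, `analysis`).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, outdir = "dyndist-run", ...) {
  base <- list(
    seed = as.integer(seed),
    outdir = outdir,
    units = list(length = "angstrom", time = "fs", energy = "kJ/mol",
                 mass = "amu", temperature = "K"),
    structure = list(seq1 = "GAGGGATAGAAAG", modify_at = 7L, hg = TRUE,
                     parallel = TRUE, isoG = TRUE, neutralize = TRUE),
    md = list(dt = 0.5, temperature = 300, thermostat = "nhc",
              chain_length = 3L, tau = 1000, friction = 0.002),
    zip = list(D_start = 1.88, D_end = 1.56, steps = 10000L),
    anneal = list(factor = 0.99, steps = 30000L, rescale_every = 100L),
    ti = list(variant = "DNA", schedule = "3.4:6.2:0.2",
              min_steps = 2000L, equilibration_fraction = 0.2,
              pre_steps = 1000L),
    analysis = list(dist_cutoff = 2.6, debounce = 3L)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(base[[nm]])) {
      base[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      base[[nm]] <- ov[[nm]]
    }
  }
  structure(base, class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param file YAML path.
#' @return `read_run_config`: a `run_config`; `write_run_config`: the
#'   path, invisibly.
#' @export
read_run_config <- function(file) {
  do.call(run_config, yaml::read_yaml(file))
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

.thermostat_from <- function(md) {
  switch(md$thermostat,
         nhc = nose_hoover_chain(md$chain_length, md$tau),
         langevin = langevin_thermostat(md$friction),
         none = NULL,
         stop("unknown thermostat type '", md$thermostat, "'"))
}

#' Run the full pipeline
#'
#' build -> zip-up -> simulated annealing -> thermodynamic integration
#' -> structural analyses, writing all traces, the resolved
#' configuration and a hash manifest into the run directory.  Re-running
#' with the same configuration reproduces the outputs bit-identically.
#'
#' @param config a `run_config` (or path to a YAML file).
#' @param quiet suppress stage messages.
#' @return invisibly, a list with the output directory, the manifest and
#'   the stage results.
#' @export
pipeline_run <- function(config = run_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  ## fail fast on an unusable schedule, before any MD has run
  parse_schedule(config$ti$schedule)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package = "dyndist",
                   version = as.character(utils::packageVersion("dyndist")),
                   seed = config$seed, stages = list(), files = list())
  stage_seed <- function(k) config$seed + 1000L * k
  results <- list()
  write_run_config(config, file.path(out, "config.yml"))

  run_stage <- function(name, fun) {
    r <- tryCatch(fun(), error = function(e) e)
    ok <- !inherits(r, "error")
    manifest$stages[[name]] <<- if (ok) "ok" else
      paste("failed:", conditionMessage(r))
    if (!ok) say("stage %s failed: %s", name, conditionMessage(r))
    if (ok) r else NULL
  }

  ## -- build
  duplex <- run_stage("build", function() {
    st <- config$structure
    d <- build_antiparallel_duplex(st$seq1)
    if (isTRUE(st$parallel)) d <- parallelize(d)
    if (isTRUE(st$isoG)) d <- guanine_to_isoguanine(d)
    if (!is.null(st$modify_at)) {
      d <- insert_modified_pair(d, st$modify_at,
                                modified_pair_template(hg = isTRUE(st$hg)))
    }
    if (isTRUE(st$neutralize)) d <- neutralize(d, seed = stage_seed(1L))
    write_pdb_duplex(d, file.path(out, "model.pdb"))
    say("build: %d bp %s duplex, net charge %+d", nrow(d$pairing),
        d$orientation, duplex_net_charge(d))
    d
  })
  if (is.null(duplex)) return(.finish_manifest(manifest, out, results))
  results$duplex <- duplex
  topo <- duplex_topology(duplex)
  thermo <- .thermostat_from(config$md)

  ## -- zip-up (modified pair held fixed, as during equilibration)
  zres <- run_stage("zip_up", function() {
    conf <- duplex_configuration(duplex, freeze_modified = TRUE)
    conf <- maxwell_boltzmann(conf, config$md$temperature,
                              seed = stage_seed(2L))
    spec <- select_constraint_pairs(duplex, "EQUI")
    z <- zip_up(topo, conf, spec, D_start = config$zip$D_start,
                D_end = config$zip$D_end, steps = config$zip$steps,
                dt = config$md$dt, thermostat = thermo,
                temperature = config$md$temperature,
                seed = stage_seed(3L))
    write_csv_trace(z$trace, file.path(out, "zip_trace.csv"))
    say("zip-up: D = %.4f Å after %d steps",
        z$trace$D[nrow(z$trace)], config$zip$steps)
    z
  })
  if (is.null(zres)) return(.finish_manifest(manifest, out, results))
  results$zip <- zres

  ## -- simulated annealing
  ares <- run_stage("anneal", function() {
    spec <- select_constraint_pairs(duplex, "EQUI")
    r <- anneal(topo, zres$conf, start_T = config$md$temperature,
                factor = config$anneal$factor,
                steps = config$anneal$steps,
                rescale_every = config$anneal$rescale_every,
                dt = config$md$dt, thermostat = thermo,
                spec = spec, target = config$zip$D_end,
                seed = stage_seed(4L))
    if (!is.null(r$trace)) {
      write_csv_trace(r$trace, file.path(out, "anneal_trace.csv"))
    }
    say("anneal: final target %.2f K", r$final_T)
    r
  })
  if (is.null(ares)) return(.finish_manifest(manifest, out, results))

  ## -- thermodynamic integration (all atoms free)
  tires <- run_stage("ti", function() {
    conf <- duplex_configuration(duplex, freeze_modified = FALSE)
    conf$pos <- ares$conf$pos
    conf <- maxwell_boltzmann(conf, config$md$temperature,
                              seed = stage_seed(5L))
    spec <- select_constraint_pairs(duplex, config$ti$variant)
    ti <- run_ti(topo, conf, spec,
                 window_schedule(parse_schedule(config$ti$schedule)$points,
                                 config$ti$min_steps,
                                 config$ti$equilibration_fraction),
                 dt = config$md$dt, thermostat = thermo,
                 temperature = config$md$temperature,
                 pre_steps = config$ti$pre_steps,
                 seed = stage_seed(6L), keep_frames = TRUE)
    write_csv_trace(ti$windows, file.path(out, "ti_windows.csv"))
    write_csv_trace(ti$profile, file.path(out, "ti_profile.csv"))
    for (k in seq_along(ti$traces)) {
      if (is.null(ti$traces[[k]])) next
      write_csv_trace(data.frame(step = seq_along(ti$traces[[k]]),
                                 lambda = ti$traces[[k]]),
                      file.path(out, sprintf("ti_lambda_w%02d.csv", k)))
    }
    n <- length(ti$profile$delta_A)
    say("TI: %d windows, ΔA(end) = %.2f kJ/mol", n,
        if (n) ti$profile$delta_A[n] else NA)
    ti
  })
  results$ti <- tires

  ## -- analyses on the TI window frames
  if (!is.null(tires)) {
    run_stage("analysis", function() {
      smap <- duplex_site_map(duplex)
      frames <- Filter(Negate(is.null), tires$frames)
      pt <- pattern_timeseries(frames, smap,
                               dist_cutoff = config$analysis$dist_cutoff,
                               debounce = config$analysis$debounce)
      utils::write.csv(data.frame(frame = seq_along(pt$labels),
                                  label = pt$labels,
                                  filtered = pt$filtered),
                       file.path(out, "patterns.csv"),
                       row.names = FALSE)
      mp <- .modified_pair_resids(smap, .frame_positions(frames[[1L]]))
      c1a <- sprintf("T%d-C1'", mp$T); c1b <- sprintf("eA%d-C1'", mp$eA)
      tr <- pair_distance_trace(frames, smap, c1a, c1b)
      utils::write.csv(data.frame(frame = seq_along(tr$dist),
                                  c1_c1 = tr$dist),
                       file.path(out, "c1_distance.csv"),
                       row.names = FALSE)
      say("analysis: %d transitions, C1'...C1' median %.2f Å",
          pt$transitions, tr$median)
      list(patterns = pt, c1 = tr)
    })
  }
  .finish_manifest(manifest, out, results)
}

.finish_manifest <- function(manifest, out, results) {
  files <- list.files(out, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  hashes <- tools::md5sum(files)
  manifest$files <- as.list(stats::setNames(unname(hashes),
                                            basename(files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(outdir = out, manifest = manifest, results = results))
}
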