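#' Save and load field states
#'
#' A `field_state` is persisted together with the parameter set and seed
#' that produced it, so every artifact is self-describing.  Round trips
#' are bit-identical.
#'
#' @param state A `field_state`.
#' @param path Output file path (RDS container).
#' @param params Optional [model_params()] to embed.
#' @return `path` invisibly (for `write_state`); the state with attribute
#'   `params` (for `read_state`).
#' @export
write_state <- function(state, path, params = NULL) {
  stopifnot(inherits(state, "field_state"))
  saveRDS(list(state = state, params = params,
               package_version = as.character(utils::packageVersion("wntpattern"))),
          path)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  obj <- readRDS(path)
  st <- obj$state
  attr(st, "params") <- obj$params
  st
}

#' Read a grayscale image for the spot pipeline
#'
#' Reads a PNG or TIFF image, averaging channels of colour images, and
#' returns intensities on the 0-255 scale.
#'
#' @param path Image file.
#' @return A numeric matrix in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3) d <- apply(d, c(1, 2), mean)
  if (max(d) <= 1) d <- d * 255
  unclass(d)
}

cli_args_to_list <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (i == length(argv) || startsWith(argv[i + 1], "--")) {
      out[[key]] <- TRUE
      i <- i + 1
    } else {
      out[[key]] <- argv[i + 1]
      i <- i + 2
    }
  }
  out
}

cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

cli_log <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), "wntpattern: ", ...)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `stability-scan`,
#' `analyze-spots`, `therapy-scan` and `synth`; see the package README
#' for usage.  Designed to be called from an `Rscript` wrapper with
#' `commandArgs(trailingOnly = TRUE)`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code (0 on success, 2 on usage errors).
#' @export
cli <- function(argv) {
  usage <- paste(
    "usage: wntpattern <command> [--key value ...]",
    "commands:",
    "  simulate       --params FILE --grid N --tend T --dt DT --seed S --out FILE",
    "                 [--mode invivo|invitro] [--snapshot-every T]",
    "  stability-scan --params FILE --param NAME --range LO:HI:N --out CSV",
    "  analyze-spots  --image FILE --pixel-size UM [--threshold otsu|VALUE]",
    "                 [--group-dist UM] [--invert] --out CSV",
    "  therapy-scan   --params FILE --state FILE --xav F1,F2,... --dca R1,R2,...",
    "                 [--duration T] --out CSV",
    "  synth          --n N [--size PX] [--noise SD] [--seed S] --out TIFF",
    "                 [--truth CSV]",
    sep = "\n")
  if (length(argv) < 1) { message(usage); return(2L) }
  cmd <- argv[1]
  opts <- tryCatch(cli_args_to_list(argv[-1]), error = function(e) NULL)
  if (is.null(opts)) { message(usage); return(2L) }
  load_p <- function() {
    if (is.null(opts$params)) mock_params() else load_params(opts$params)
  }
  ok <- tryCatch({
    switch(cmd,
      "simulate" = {
        p <- load_p()
        n <- as.integer(cli_num(opts, "grid", 128))
        seed <- as.integer(cli_num(opts, "seed", 1))
        tend <- cli_num(opts, "tend", 200)
        dt <- cli_num(opts, "dt", 5e-4)
        mode <- if (is.null(opts$mode)) "invivo" else opts$mode
        cli_log("simulate mode=", mode, " grid=", n, " tend=", tend,
                " seed=", seed)
        if (mode == "invitro") {
          res <- simulate_colony(invitro_params(p), grid = sim_grid(n),
                                 seed = seed, t_end = tend, dt = dt)
          write_state(res$state, opts$out, params = res$params)
        } else {
          res <- simulate_model(p, grid = sim_grid(n, 2, c(p$S_x, p$S_y)),
                                t_end = tend, dt = dt, seed = seed)
          write_state(res$state, opts$out, params = p)
        }
        cli_log("wrote ", opts$out)
        TRUE
      },
      "stability-scan" = {
        p <- load_p()
        rng <- as.numeric(strsplit(opts$range, ":")[[1]])
        values <- seq(rng[1], rng[2], length.out = rng[3])
        tab <- parameter_effect_scan(p, opts$param, values,
                                     grid = sim_grid(as.integer(cli_num(opts, "grid", 96))),
                                     t_end = cli_num(opts, "tend", 80))
        utils::write.csv(tab, opts$out, row.names = FALSE)
        cli_log("wrote ", opts$out)
        TRUE
      },
      "analyze-spots" = {
        img <- read_gray_image(opts$image)
        px <- cli_num(opts, "pixel-size", 1)
        thr <- opts$threshold
        invert <- isTRUE(opts$invert)
        mask <- if (is.null(thr) || identical(thr, "otsu"))
          binarize(img, "otsu", invert = invert)
        else binarize(img, "manual", threshold = as.numeric(thr),
                      invert = invert)
        spots <- detect_spots(mask,
                              group_distance_px = cli_num(opts, "group-dist", 15) / px,
                              pixel_size_um = px)
        write_spots_csv(spots, opts$out)
        cli_log("wrote ", opts$out, " (", nrow(spots$spots), " spots)")
        TRUE
      },
      "therapy-scan" = {
        p <- load_p()
        state <- read_state(opts$state)
        xav <- as.numeric(strsplit(opts$xav, ",")[[1]])
        dca <- as.numeric(strsplit(opts$dca, ",")[[1]])
        res <- therapy_surface(p, state, xav, dca,
                               duration = cli_num(opts, "duration", 50),
                               dt = cli_num(opts, "dt", 1e-3))
        utils::write.csv(res$surface, opts$out, row.names = FALSE)
        cli_log("wrote ", opts$out)
        TRUE
      },
      "synth" = {
        spec <- synthetic_image_spec(
          size_px = as.integer(cli_num(opts, "size", 256)),
          n_spots = as.integer(cli_num(opts, "n", 50)),
          noise_sd = cli_num(opts, "noise", 0),
          seed = as.integer(cli_num(opts, "seed", 1)))
        out <- make_spot_image(spec)
        EBImage::writeImage(EBImage::Image(out$image / 255), opts$out)
        if (!is.null(opts$truth))
          utils::write.csv(out$truth, opts$truth, row.names = FALSE)
        cli_log("wrote ", opts$out)
        TRUE
      },
      {
        message("unknown command: ", cmd, "\n", usage)
        FALSE
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    FALSE
  })
  if (isTRUE(ok)) 0L else 2L
}
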