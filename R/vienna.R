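#' ViennaRNA command-line thermodynamics engine
#'
#' Adapter over the RNAcofold / RNAeval / RNAplfold executables.
#' `constrained_cofold` runs RNAcofold with enforced hard constraints on
#' the nucleus pairs; `evaluate` scores a fixed structure with RNAeval;
#' `unpaired_probability` runs RNAplfold on the supplied window with
#' `-W` equal to the window length, so the reported probability is the
#' exact open probability of that single window.
#'
#' @param temperature_C folding temperature in Celsius.
#' @return an engine list (`constrained_cofold`, `evaluate`,
#'   `unpaired_probability`, `name`).
#' @export
vienna_engine <- function(temperature_C = 37) {
  for (tool in c("RNAcofold", "RNAeval", "RNAplfold")) {
    if (Sys.which(tool) == "") stop("ViennaRNA executable not found: ", tool)
  }
  Topt <- c("-T", format(temperature_C))

  run <- function(cmd, args, input) {
    out <- suppressWarnings(system2(cmd, args, stdout = TRUE, stderr = FALSE,
                                    input = input))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0L) {
      stop(cmd, " exited with status ", status, " on input: ",
           paste(input, collapse = " / "))
    }
    out
  }

  parse_energy <- function(lines) {
    ln <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", lines, value = TRUE)
    if (!length(ln)) stop("no energy in ViennaRNA output: ",
                          paste(lines, collapse = " | "))
    as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1",
                   ln[length(ln)]))
  }

  ## dot-bracket (with '&' stripped) -> pair table relative to molecules
  parse_pairs <- function(db, len_a) {
    ch <- strsplit(gsub("&", "", db, fixed = TRUE), "", fixed = TRUE)[[1L]]
    stack <- integer(0)
    pi <- integer(0); pj <- integer(0)
    for (i in seq_along(ch)) {
      if (ch[i] == "(") stack <- c(stack, i)
      else if (ch[i] == ")") {
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        pi <- c(pi, j); pj <- c(pj, i)
      }
    }
    data.frame(mol_i = ifelse(pi <= len_a, 1L, 2L),
               pos_i = ifelse(pi <= len_a, pi, pi - len_a),
               mol_j = ifelse(pj <= len_a, 1L, 2L),
               pos_j = ifelse(pj <= len_a, pj, pj - len_a))
  }

  ## pair table -> dot-bracket with '&' between molecules
  to_dotbracket <- function(structure, len_a, len_b) {
    ch <- rep(".", len_a + len_b)
    gi <- ifelse(structure$mol_i == 1L, structure$pos_i, structure$pos_i + len_a)
    gj <- ifelse(structure$mol_j == 1L, structure$pos_j, structure$pos_j + len_a)
    lo <- pmin(gi, gj); hi <- pmax(gi, gj)
    ch[lo] <- "("; ch[hi] <- ")"
    paste0(paste(ch[seq_len(len_a)], collapse = ""), "&",
           paste(ch[len_a + seq_len(len_b)], collapse = ""))
  }

  cofold <- function(seq_a, seq_b, forced_pairs) {
    la <- nchar(seq_a)
    ## hard-force the nucleus pairs through a ViennaRNA command file
    ## ("F i j 1" in concatenated coordinates)
    cmdfile <- tempfile("viennacmd", fileext = ".txt")
    on.exit(unlink(cmdfile), add = TRUE)
    writeLines(sprintf("F %d %d 1", forced_pairs$mirna_pos,
                       la + forced_pairs$context_pos), cmdfile)
    out <- run("RNAcofold",
               c(paste0("--commands=", cmdfile), "--noPS", Topt),
               paste0(seq_a, "&", seq_b))
    db <- sub("\\s.*$", "", out[2L])
    list(structure = parse_pairs(db, la), energy = parse_energy(out))
  }

  eval_struct <- function(seq_a, seq_b, structure) {
    db <- to_dotbracket(structure, nchar(seq_a), nchar(seq_b))
    out <- run("RNAeval", Topt, c(paste0(seq_a, "&", seq_b), db))
    parse_energy(out)
  }

  unpaired <- function(window_seq, region_start, region_end, max_span) {
    ulen <- region_end - region_start
    if (ulen <= 0L) return(1)
    n <- nchar(window_seq)
    dir <- tempfile("plfold")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    old <- setwd(dir); on.exit(setwd(old), add = TRUE)
    run("RNAplfold",
        c("-W", n, "-L", min(max_span, n), "-u", ulen, Topt),
        c(">w", window_seq))
    lunp <- utils::read.table("w_lunp", comment.char = "#",
                              fill = TRUE, na.strings = "NA")
    row <- lunp[lunp[[1L]] == region_end, , drop = FALSE]
    p <- as.numeric(row[[ulen + 1L]])
    if (!is.finite(p)) stop("RNAplfold returned no probability for region [",
                            region_start, ",", region_end, ")")
    p
  }

  list(name = sprintf("vienna(T=%gC)", temperature_C),
       constrained_cofold = cofold,
       evaluate = eval_struct,
       unpaired_probability = unpaired)
}
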