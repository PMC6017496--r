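#' Scatter of selected decoys in the (lRMSD, energy) plane
#'
#' All decoys are drawn in grey by their distance to the native (x axis,
#' Angstrom) and energy (y axis); the decoys of the top-x selected groups
#' are overlaid in color, one color per group.
#'
#' @param ds a [DecoySet-class] with native information
#' @param sel a [RankedGroups-class]
#' @param file optional output path (written with [ggplot2::ggsave()])
#' @return the ggplot object, invisibly when written to file
#' @export
plotSelection <- function(ds, sel, file = NULL) {
  stopifnot(is(ds, "DecoySet"), is(sel, "RankedGroups"))
  nd <- unname(nativeDistances(ds))
  en <- unname(energies(ds))
  all_df <- data.frame(lrmsd = nd, energy = en)
  grp <- do.call(rbind, lapply(seq_along(sel@groups), function(k)
    data.frame(lrmsd = nd[sel@groups[[k]]], energy = en[sel@groups[[k]]],
               group = paste0("G", k))))
  p <- ggplot2::ggplot(all_df, ggplot2::aes(x = .data$lrmsd,
                                            y = .data$energy)) +
    ggplot2::geom_point(color = "grey70", size = 0.8) +
    ggplot2::geom_point(data = grp, ggplot2::aes(color = .data$group),
                        size = 1.2) +
    ggplot2::labs(x = "lRMSD to native (Å)", y = "energy",
                  color = "group",
                  title = paste("Selected decoys:", sel@strategy)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Basin disks in the (stability, focal energy) plane
#'
#' Each basin is a disk placed at its stability (x) and focal energy (y);
#' disk area is proportional to basin size, and color encodes the basin's
#' purity (fraction of native-labelled members) from blue (impure) to red
#' (pure). Basins selected by a strategy can be outlined. Basins with
#' infinite stability (no escape saddle) are drawn as open squares at a
#' sentinel position right of the finite range, noted in the x-axis label.
#'
#' @param bs a [BasinSet-class] with stability computed
#' @param labels logical native labels from [labelNatives()]
#' @param selected optional integer vector of basin ids to outline
#' @param file optional output path
#' @return the ggplot object, invisibly when written to file
#' @export
plotBasinDisks <- function(bs, labels, selected = NULL, file = NULL) {
  stopifnot(is(bs, "BasinSet"), is.logical(labels))
  b <- basinTable(bs)
  if (anyNA(b$stability))
    stop("compute saddles and stability before plotting basin disks")
  purity <- vapply(b$basin, function(bi)
    mean(labels[bs@assignment == bi]), numeric(1))
  fin <- is.finite(b$stability)
  sentinel <- if (any(fin)) max(b$stability[fin]) * 1.15 + 0.1 else 1
  df <- data.frame(stability = ifelse(fin, b$stability, sentinel),
                   energy = b$focalEnergy, size = b$size, purity = purity,
                   infinite = !fin,
                   selected = b$basin %in% (selected %||% integer(0)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stability,
                                        y = .data$energy)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$size,
                                     fill = .data$purity,
                                     shape = .data$infinite),
                        color = "grey30", alpha = 0.9) +
    ggplot2::geom_point(data = df[df$selected, , drop = FALSE],
                        ggplot2::aes(size = .data$size), shape = 0,
                        color = "black", stroke = 1.1) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 21, `TRUE` = 22),
                                labels = c("finite", "infinite (sentinel)"),
                                name = "stability") +
    ggplot2::scale_fill_gradient(low = "blue", high = "red",
                                 limits = c(0, 1), name = "purity") +
    ggplot2::scale_size_area(max_size = 12, name = "basin size") +
    ggplot2::labs(
      x = "stability (infinite-stability basins at sentinel position)",
      y = "focal energy") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6.5, height = 4.5, dpi = 150)
    return(invisible(p))
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
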