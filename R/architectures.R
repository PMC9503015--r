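# Layer graphs: CNN-a and the four from-scratch reference networks.
#
# All networks take single-channel (grayscale) input and emit two class
# scores. CNN-a is the AlexNet topology with every channel-wise local
# response normalization replaced by batch normalization and one extra
# 3x3/stride-2/pad-0 max-pooling layer inserted between the adjacent pair
# of grouped convolutions (conv4/conv5). Where the reference prints no
# value, stock channel widths are retained. Convolution paddings follow
# the widely used AlexNet parameterization (conv1 pad 2), under which the
# minimum viable CNN-a input is 128 pixels.

alexnetNodes <- function(variant = c("alexnet", "cnn_a"), nClasses = 2L,
                         dropP = 0.5) {
  variant <- match.arg(variant)
  bn <- variant == "cnn_a"
  norm <- function(name, from) {
    if (bn) nd(name, "bn", from)
    else nd(name, "lrn", from, nwin = 5L, alpha = 1e-4, beta = 0.75, k = 2)
  }
  nodes <- list(
    nd("input", "input", character()),
    nd("conv1", "conv", "input", kernel = 11L, stride = 4L, pad = 2L,
       outChannels = 96L, groups = 1L),
    nd("relu1", "relu", "conv1"),
    norm("norm1", "relu1"),
    nd("pool1", "maxpool", "norm1", kernel = 3L, stride = 2L, pad = 0L),
    nd("conv2", "conv", "pool1", kernel = 5L, stride = 1L, pad = 2L,
       outChannels = 256L, groups = 2L),
    nd("relu2", "relu", "conv2"),
    norm("norm2", "relu2"),
    nd("pool2", "maxpool", "norm2", kernel = 3L, stride = 2L, pad = 0L),
    nd("conv3", "conv", "pool2", kernel = 3L, stride = 1L, pad = 1L,
       outChannels = 384L, groups = 1L),
    nd("relu3", "relu", "conv3"),
    nd("conv4", "conv", "relu3", kernel = 3L, stride = 1L, pad = 1L,
       outChannels = 384L, groups = 2L),
    nd("relu4", "relu", "conv4"))
  conv5From <- "relu4"
  if (variant == "cnn_a") {
    nodes <- c(nodes, list(
      nd("pool_new", "maxpool", "relu4", kernel = 3L, stride = 2L, pad = 0L)))
    conv5From <- "pool_new"
  }
  c(nodes, list(
    nd("conv5", "conv", conv5From, kernel = 3L, stride = 1L, pad = 1L,
       outChannels = 256L, groups = 2L),
    nd("relu5", "relu", "conv5"),
    nd("pool5", "maxpool", "relu5", kernel = 3L, stride = 2L, pad = 0L),
    nd("flatten", "flatten", "pool5"),
    nd("fc6", "fc", "flatten", outFeatures = 4096L),
    nd("relu6", "relu", "fc6"),
    nd("drop6", "dropout", "relu6", p = dropP),
    nd("fc7", "fc", "drop6", outFeatures = 4096L),
    nd("relu7", "relu", "fc7"),
    nd("drop7", "dropout", "relu7", p = dropP),
    nd("fc8", "fc", "drop7", outFeatures = as.integer(nClasses))))
}

inceptionNodes <- function(id, from, ch1, ch3red, ch3, ch5red, ch5, pool) {
  p <- function(s) paste0("inc", id, "_", s)
  cb <- function(name, from, out, k, pad) list(
    nd(p(name), "conv", from, kernel = as.integer(k), stride = 1L,
       pad = as.integer(pad), outChannels = as.integer(out), groups = 1L),
    nd(p(paste0(name, "_bn")), "bn", p(name)),
    nd(p(paste0(name, "_relu")), "relu", p(paste0(name, "_bn"))))
  c(
    cb("b1", from, ch1, 1L, 0L),
    cb("b2a", from, ch3red, 1L, 0L),
    cb("b2b", p("b2a_relu"), ch3, 3L, 1L),
    cb("b3a", from, ch5red, 1L, 0L),
    cb("b3b", p("b3a_relu"), ch5, 5L, 2L),
    list(nd(p("b4pool"), "maxpool", from, kernel = 3L, stride = 1L, pad = 1L)),
    cb("b4", p("b4pool"), pool, 1L, 0L),
    list(nd(p("out"), "concat",
            c(p("b1_relu"), p("b2b_relu"), p("b3b_relu"), p("b4_relu")))))
}

googlenetNodes <- function(nClasses = 2L) {
  cb <- function(name, from, out, k, s, pad) list(
    nd(name, "conv", from, kernel = as.integer(k), stride = as.integer(s),
       pad = as.integer(pad), outChannels = as.integer(out), groups = 1L),
    nd(paste0(name, "_bn"), "bn", name),
    nd(paste0(name, "_relu"), "relu", paste0(name, "_bn")))
  nodes <- c(
    list(nd("input", "input", character())),
    cb("conv1", "input", 64L, 7L, 2L, 3L),
    list(nd("pool1", "maxpool", "conv1_relu", kernel = 3L, stride = 2L, pad = 1L)),
    cb("conv2", "pool1", 64L, 1L, 1L, 0L),
    cb("conv3", "conv2_relu", 192L, 3L, 1L, 1L),
    list(nd("pool2", "maxpool", "conv3_relu", kernel = 3L, stride = 2L, pad = 1L)),
    inceptionNodes("3a", "pool2", 64, 96, 128, 16, 32, 32),
    inceptionNodes("3b", "inc3a_out", 128, 128, 192, 32, 96, 64),
    list(nd("pool3", "maxpool", "inc3b_out", kernel = 3L, stride = 2L, pad = 1L)),
    inceptionNodes("4a", "pool3", 192, 96, 208, 16, 48, 64),
    inceptionNodes("4b", "inc4a_out", 160, 112, 224, 24, 64, 64),
    inceptionNodes("4c", "inc4b_out", 128, 128, 256, 24, 64, 64),
    inceptionNodes("4d", "inc4c_out", 112, 144, 288, 32, 64, 64),
    inceptionNodes("4e", "inc4d_out", 256, 160, 320, 32, 128, 128),
    list(nd("pool4", "maxpool", "inc4e_out", kernel = 3L, stride = 2L, pad = 1L)),
    inceptionNodes("5a", "pool4", 256, 160, 320, 32, 128, 128),
    inceptionNodes("5b", "inc5a_out", 384, 192, 384, 48, 128, 128),
    list(nd("gap", "gap", "inc5b_out"),
         nd("drop", "dropout", "gap", p = 0.4),
         nd("fc", "fc", "drop", outFeatures = as.integer(nClasses))))
  nodes
}

resnetBlock <- function(id, from, out, stride, downsample) {
  p <- function(s) paste0(id, "_", s)
  nodes <- list(
    nd(p("conv1"), "conv", from, kernel = 3L, stride = as.integer(stride),
       pad = 1L, outChannels = as.integer(out), groups = 1L),
    nd(p("bn1"), "bn", p("conv1")),
    nd(p("relu1"), "relu", p("bn1")),
    nd(p("conv2"), "conv", p("relu1"), kernel = 3L, stride = 1L, pad = 1L,
       outChannels = as.integer(out), groups = 1L),
    nd(p("bn2"), "bn", p("conv2")))
  shortcut <- from
  if (downsample) {
    nodes <- c(nodes, list(
      nd(p("down"), "conv", from, kernel = 1L, stride = as.integer(stride),
         pad = 0L, outChannels = as.integer(out), groups = 1L),
      nd(p("down_bn"), "bn", p("down"))))
    shortcut <- p("down_bn")
  }
  c(nodes, list(
    nd(p("add"), "add", c(p("bn2"), shortcut)),
    nd(p("out"), "relu", p("add"))))
}

resnet18Nodes <- function(nClasses = 2L) {
  c(
    list(nd("input", "input", character()),
         nd("conv1", "conv", "input", kernel = 7L, stride = 2L, pad = 3L,
            outChannels = 64L, groups = 1L),
         nd("bn1", "bn", "conv1"),
         nd("relu1", "relu", "bn1"),
         nd("pool1", "maxpool", "relu1", kernel = 3L, stride = 2L, pad = 1L)),
    resnetBlock("l1b1", "pool1", 64L, 1L, FALSE),
    resnetBlock("l1b2", "l1b1_out", 64L, 1L, FALSE),
    resnetBlock("l2b1", "l1b2_out", 128L, 2L, TRUE),
    resnetBlock("l2b2", "l2b1_out", 128L, 1L, FALSE),
    resnetBlock("l3b1", "l2b2_out", 256L, 2L, TRUE),
    resnetBlock("l3b2", "l3b1_out", 256L, 1L, FALSE),
    resnetBlock("l4b1", "l3b2_out", 512L, 2L, TRUE),
    resnetBlock("l4b2", "l4b1_out", 512L, 1L, FALSE),
    list(nd("gap", "gap", "l4b2_out"),
         nd("fc", "fc", "gap", outFeatures = as.integer(nClasses))))
}

fireNodes <- function(id, from, squeeze, expand) {
  p <- function(s) paste0(id, "_", s)
  list(
    nd(p("sq"), "conv", from, kernel = 1L, stride = 1L, pad = 0L,
       outChannels = as.integer(squeeze), groups = 1L),
    nd(p("sq_relu"), "relu", p("sq")),
    nd(p("e1"), "conv", p("sq_relu"), kernel = 1L, stride = 1L, pad = 0L,
       outChannels = as.integer(expand), groups = 1L),
    nd(p("e1_relu"), "relu", p("e1")),
    nd(p("e3"), "conv", p("sq_relu"), kernel = 3L, stride = 1L, pad = 1L,
       outChannels = as.integer(expand), groups = 1L),
    nd(p("e3_relu"), "relu", p("e3")),
    nd(p("out"), "concat", c(p("e1_relu"), p("e3_relu"))))
}

squeezenetNodes <- function(nClasses = 2L) {
  c(
    list(nd("input", "input", character()),
         nd("conv1", "conv", "input", kernel = 3L, stride = 2L, pad = 0L,
            outChannels = 64L, groups = 1L),
         nd("relu1", "relu", "conv1"),
         nd("pool1", "maxpool", "relu1", kernel = 3L, stride = 2L, pad = 0L)),
    fireNodes("fire2", "pool1", 16L, 64L),
    fireNodes("fire3", "fire2_out", 16L, 64L),
    list(nd("pool3", "maxpool", "fire3_out", kernel = 3L, stride = 2L, pad = 0L)),
    fireNodes("fire4", "pool3", 32L, 128L),
    fireNodes("fire5", "fire4_out", 32L, 128L),
    list(nd("pool5", "maxpool", "fire5_out", kernel = 3L, stride = 2L, pad = 0L)),
    fireNodes("fire6", "pool5", 48L, 192L),
    fireNodes("fire7", "fire6_out", 48L, 192L),
    fireNodes("fire8", "fire7_out", 64L, 256L),
    fireNodes("fire9", "fire8_out", 64L, 256L),
    list(nd("drop", "dropout", "fire9_out", p = 0.5),
         nd("conv10", "conv", "drop", kernel = 1L, stride = 1L, pad = 0L,
            outChannels = as.integer(nClasses), groups = 1L),
         nd("relu10", "relu", "conv10"),
         nd("gap", "gap", "relu10")))
}

ARCH_NAMES <- c("cnn_a", "alexnet", "googlenet", "resnet18", "squeezenet")

archNodes <- function(name, nClasses = 2L) {
  switch(name,
    cnn_a = alexnetNodes("cnn_a", nClasses),
    alexnet = alexnetNodes("alexnet", nClasses),
    googlenet = googlenetNodes(nClasses),
    resnet18 = resnet18Nodes(nClasses),
    squeezenet = squeezenetNodes(nClasses),
    stop("unknown architecture: ", name))
}

#' Build CNN-a
#'
#' Constructs the AlexNet-derived architecture: every local response
#' normalization layer replaced by batch normalization, one additional
#' 3x3 max-pooling layer (stride 2, pad 0) inserted between the two
#' grouped convolutions conv4 and conv5, single-channel input and a
#' two-way classifier head. Weights are randomly initialized (fan-in
#' scaled) under \code{seed}, so two builds with the same seed are
#' identical.
#'
#' @param inputSize input side in pixels (desk default 128, full 512; the
#'   layer chain requires at least 128).
#' @param nClasses number of output classes (default 2).
#' @param seed initialization seed.
#' @return A \code{\linkS4class{CNNModel}}.
#' @export
#' @examples
#' m <- buildCNNa(128)
#' head(layerTable(m))
buildCNNa <- function(inputSize = 128L, nClasses = 2L, seed = 1L) {
  buildModel("cnn_a", archNodes("cnn_a", nClasses), inputSize, nClasses, seed)
}

#' Build a from-scratch reference architecture
#'
#' Instantiates AlexNet, GoogLeNet (inception v1, batch-norm stem, no
#' auxiliary heads), ResNet18 or SqueezeNet (v1.1 layout) -- or CNN-a --
#' with random initial weights (never pretrained), grayscale input and a
#' two-way output.
#'
#' @param name one of \code{"cnn_a"}, \code{"alexnet"}, \code{"googlenet"},
#'   \code{"resnet18"}, \code{"squeezenet"}.
#' @param inputSize input side in pixels.
#' @param nClasses number of output classes (default 2).
#' @param seed initialization seed.
#' @return A \code{\linkS4class{CNNModel}}.
#' @export
buildReference <- function(name, inputSize = 128L, nClasses = 2L, seed = 1L) {
  if (!(name %in% ARCH_NAMES))
    stop("unknown architecture: ", name,
         " (supported: ", paste(ARCH_NAMES, collapse = ", "), ")")
  buildModel(name, archNodes(name, nClasses), inputSize, nClasses, seed)
}

#' Human-readable layer table of a model
#'
#' Serializes the layer graph for inspection and diffing: one row per
#' layer with kind, kernel/stride/pad, groups, output shape and inputs.
#'
#' @param model a \code{CNNModel}.
#' @return data.frame.
#' @export
layerTable <- function(model) {
  sh <- model@state$shapes
  rows <- lapply(model@nodes, function(node) {
    s <- sh[[node$name]]
    data.frame(
      name = node$name, kind = node$op,
      kernel = if (!is.null(node$kernel)) node$kernel else NA_integer_,
      stride = if (!is.null(node$stride)) node$stride else NA_integer_,
      pad = if (!is.null(node$pad)) node$pad else NA_integer_,
      groups = if (!is.null(node$groups)) node$groups else NA_integer_,
      outH = if (!is.null(s$H)) s$H else NA_integer_,
      outW = if (!is.null(s$W)) s$W else NA_integer_,
      outC = if (!is.null(s$C)) s$C else (if (!is.null(s$F)) s$F else NA_integer_),
      inputs = paste(node$inputs, collapse = "+"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the layer table to a plain-text file
#' @param model a \code{CNNModel}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeLayerTable <- function(model, path) {
  utils::write.csv(layerTable(model), path, row.names = FALSE)
  invisible(path)
}

#' Save / load model checkpoints
#'
#' Checkpoints store the architecture name, input size, weights and
#' batch-norm running statistics; gather caches are rebuilt on load.
#'
#' @param model a \code{CNNModel}.
#' @param path checkpoint file (RDS).
#' @return \code{loadModel} returns the restored \code{CNNModel}.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(arch = model@arch, inputSize = model@inputSize,
               nClasses = model@nClasses, weights = model@weights,
               running = model@state$running), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  m <- buildReference(x$arch, x$inputSize, x$nClasses, seed = 1L)
  m@weights <- x$weights
  m@state$running <- x$running
  m
}
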