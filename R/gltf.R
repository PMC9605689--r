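# Minimal glTF 2.0 scene I/O.
#
# Reads and writes the subset of glTF used for experimental scenes: triangle
# meshes (POSITION / TEXCOORD_0 / indices accessors), unlit flat or textured
# materials (baseColorFactor / baseColorTexture with PNG images), node TRS or
# matrix transforms, and perspective/orthographic cameras. Compound-eye
# cameras are marked in each camera's reserved "extras" property with the keys
#   compound-eye: true
#   compound-structure: <eye CSV path, relative to the glTF file>
#   compound-projection: <display projection hint>
# Panoramic debug cameras are stored as perspective cameras with an extras
# flag, since glTF itself has no panoramic type.
#
# Units: glTF coordinates are treated as millimetres throughout.
# Camera orientation: glTF cameras look along -z; package poses look along +z.
# A 180-degree rotation about +y is composed on write and removed on read.

GLTF_COMP <- c(`5120` = 1L, `5121` = 1L, `5122` = 2L, `5123` = 2L,
               `5125` = 4L, `5126` = 4L)
GLTF_NCOMP <- c(SCALAR = 1L, VEC2 = 2L, VEC3 = 3L, VEC4 = 4L, MAT4 = 16L)
QUAT_Y180 <- c(0, 0, 1, 0)  # (w, x, y, z)

data_uri <- function(raw, mime = "application/octet-stream") {
  paste0("data:", mime, ";base64,", jsonlite::base64_enc(raw))
}

decode_uri_or_file <- function(uri, dir) {
  if (grepl("^data:", uri)) {
    jsonlite::base64_dec(gsub("\\s", "", sub("^data:[^,]*,", "", uri)))
  } else {
    f <- file.path(dir, utils::URLdecode(uri))
    if (!file.exists(f)) stopf("glTF references missing file '%s'", f)
    readBin(f, "raw", file.info(f)$size)
  }
}

#' Write a scene to a glTF 2.0 file
#'
#' Geometry is stored as float32 accessors in a single embedded
#' (base64 data URI) buffer; textures as embedded PNG images. Camera extras
#' carry the compound-eye markers read back by [load_gltf()].
#'
#' @param sc an [scene()].
#' @param path output file (`.gltf`).
#' @return `path`, invisibly.
#' @export
save_gltf <- function(sc, path) {
  stopifnot(inherits(sc, "eye_scene"))
  buf <- raw(0)
  views <- list()
  accessors <- list()
  add_view <- function(bytes) {
    views[[length(views) + 1L]] <<- list(buffer = 0L,
                                         byteOffset = length(buf),
                                         byteLength = length(bytes))
    buf <<- c(buf, bytes)
    length(views) - 1L
  }
  add_accessor <- function(data, type, component, minmax = FALSE) {
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con), add = TRUE)
    if (component == 5126L) {
      writeBin(as.numeric(t(data)), con, size = 4L, endian = "little")
    } else {
      writeBin(as.integer(t(data)), con, size = 4L, endian = "little")
    }
    v <- add_view(rawConnectionValue(con))
    acc <- list(bufferView = v, componentType = component,
                count = if (is.matrix(data)) nrow(data) else length(data),
                type = type)
    if (minmax) {
      acc$min <- as.numeric(apply(data, 2, min))
      acc$max <- as.numeric(apply(data, 2, max))
    }
    accessors[[length(accessors) + 1L]] <<- acc
    length(accessors) - 1L
  }

  images <- list()
  textures <- list()
  materials <- list()
  for (k in seq_along(sc$materials)) {
    m <- sc$materials[[k]]
    mat <- list(pbrMetallicRoughness = list(
      baseColorFactor = c(m$base_colour, 1),
      metallicFactor = 0, roughnessFactor = 1))
    if (!is.null(m$texture)) {
      con <- rawConnection(raw(0), "wb")
      png::writePNG(m$texture, con)
      bytes <- rawConnectionValue(con)
      close(con)
      images[[length(images) + 1L]] <-
        list(uri = data_uri(bytes, "image/png"))
      textures[[length(textures) + 1L]] <-
        list(source = length(images) - 1L)
      mat$pbrMetallicRoughness$baseColorTexture <-
        list(index = length(textures) - 1L)
    }
    materials[[k]] <- mat
  }

  meshes <- list()
  for (k in seq_along(sc$meshes)) {
    ms <- sc$meshes[[k]]
    prim <- list(attributes = list(
      POSITION = add_accessor(ms$vertices, "VEC3", 5126L, minmax = TRUE)),
      indices = add_accessor(as.vector(t(ms$triangles)) - 1L, "SCALAR", 5125L),
      material = k - 1L, mode = 4L)
    if (!is.null(ms$uv))
      prim$attributes$TEXCOORD_0 <- add_accessor(ms$uv, "VEC2", 5126L)
    meshes[[k]] <- list(primitives = list(prim))
  }

  nodes <- list()
  for (k in seq_along(sc$meshes))
    nodes[[length(nodes) + 1L]] <- list(mesh = k - 1L,
                                        name = sprintf("mesh%d", k))
  cameras <- list()
  for (cm in sc$cameras) {
    q <- quat_multiply(cm$pose$quaternion, QUAT_Y180)
    if (cm$kind == "orthographic") {
      cam <- list(type = "orthographic",
                  orthographic = list(xmag = cm$xmag, ymag = cm$ymag,
                                      znear = 0.001, zfar = 1e6))
    } else {
      cam <- list(type = "perspective",
                  perspective = list(yfov = cm$yfov, znear = 0.001))
    }
    if (cm$kind == "compound") {
      cam$extras <- list(`compound-eye` = TRUE,
                         `compound-structure` = cm$eye_csv,
                         `compound-projection` = cm$projection_hint)
    } else if (cm$kind == "panoramic") {
      cam$extras <- list(panoramic = TRUE)
    }
    cameras[[length(cameras) + 1L]] <- cam
    nodes[[length(nodes) + 1L]] <- list(
      camera = length(cameras) - 1L, name = cm$name,
      translation = cm$pose$position,
      rotation = c(q[2], q[3], q[4], q[1]))  # glTF order x,y,z,w
  }

  doc <- list(
    asset = list(version = "2.0", generator = "compeye"),
    scene = 0L,
    scenes = list(list(nodes = seq_along(nodes) - 1L,
                       extras = list(background = sc$background))),
    nodes = nodes,
    meshes = meshes,
    materials = materials,
    accessors = accessors,
    bufferViews = views,
    buffers = list(list(byteLength = length(buf), uri = data_uri(buf))))
  if (length(cameras)) doc$cameras <- cameras
  if (length(images)) {
    doc$images <- images
    doc$textures <- textures
    doc$samplers <- list(list(magFilter = 9729L, minFilter = 9729L))
  }
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

read_glb <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (magic != 0x46546C67) stopf("'%s' is not a GLB file", path)
  readBin(con, "integer", 2L, size = 4L, endian = "little")  # version, length
  json_txt <- NULL
  bin <- raw(0)
  repeat {
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(len)) break
    type <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    chunk <- readBin(con, "raw", len)
    if (type == 0x4E4F534A) json_txt <- rawToChar(chunk)
    else if (type == 0x004E4942) bin <- chunk
  }
  if (is.null(json_txt)) stopf("GLB file '%s' has no JSON chunk", path)
  list(json = json_txt, bin = bin)
}

gltf_read_accessor <- function(doc, buffers, idx) {
  acc <- doc$accessors[[idx + 1L]]
  if (!is.null(acc$sparse)) stopf("sparse accessors are not supported")
  comp <- GLTF_COMP[[as.character(acc$componentType)]]
  if (is.null(comp)) stopf("unsupported accessor componentType %s", acc$componentType)
  nc <- GLTF_NCOMP[[acc$type]]
  if (is.null(nc)) stopf("unsupported accessor type '%s'", acc$type)
  bv <- doc$bufferViews[[acc$bufferView + 1L]]
  elem <- comp * nc
  stride <- bv$byteStride %||% elem
  if (stride != elem) stopf("strided buffer views are not supported")
  off <- (bv$byteOffset %||% 0L) + (acc$byteOffset %||% 0L)
  bytes <- buffers[[(bv$buffer %||% 0L) + 1L]][(off + 1L):(off + elem * acc$count)]
  n <- nc * acc$count
  vals <- switch(as.character(acc$componentType),
    `5126` = readBin(bytes, "numeric", n, size = 4L, endian = "little"),
    `5125` = {
      v <- readBin(bytes, "integer", n, size = 4L, endian = "little")
      if (any(v < 0)) stopf("uint32 index above 2^31 is not supported")
      v
    },
    `5123` = readBin(bytes, "integer", n, size = 2L, signed = FALSE, endian = "little"),
    `5121` = as.integer(bytes),
    `5122` = readBin(bytes, "integer", n, size = 2L, endian = "little"),
    `5120` = readBin(bytes, "integer", n, size = 1L))
  if (nc == 1L) vals else matrix(vals, ncol = nc, byrow = TRUE)
}

gltf_node_matrix <- function(node) {
  if (!is.null(node$matrix)) return(matrix(unlist(node$matrix), 4, 4))  # column-major
  M <- diag(4)
  if (!is.null(node$scale)) M[1:3, 1:3] <- diag(unlist(node$scale))
  if (!is.null(node$rotation)) {
    r <- unlist(node$rotation)  # x, y, z, w
    M[1:3, 1:3] <- quat_to_matrix(c(r[4], r[1], r[2], r[3])) %*% M[1:3, 1:3]
  }
  if (!is.null(node$translation)) M[1:3, 4] <- unlist(node$translation)
  M
}

gltf_read_image <- function(doc, buffers, dir, idx) {
  img <- doc$images[[idx + 1L]]
  bytes <- if (!is.null(img$uri)) {
    decode_uri_or_file(img$uri, dir)
  } else {
    bv <- doc$bufferViews[[img$bufferView + 1L]]
    off <- bv$byteOffset %||% 0L
    buffers[[(bv$buffer %||% 0L) + 1L]][(off + 1L):(off + bv$byteLength)]
  }
  px <- png::readPNG(bytes)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px
}

#' Load a glTF 2.0 scene
#'
#' Meshes are triangulated into the world frame (node transforms applied);
#' cameras whose extras carry a `compound-eye` marker become compound
#' [camera_spec()]s with their eye CSV resolved relative to the glTF file.
#'
#' @param path a `.gltf` or `.glb` file.
#' @return an [scene()].
#' @export
load_gltf <- function(path) {
  if (!file.exists(path)) stopf("glTF file '%s' does not exist", path)
  dir <- dirname(path)
  glb_bin <- raw(0)
  head4 <- readBin(path, "raw", 4L)
  if (identical(rawToChar(head4), "glTF")) {
    g <- read_glb(path)
    doc <- jsonlite::fromJSON(g$json, simplifyVector = FALSE)
    glb_bin <- g$bin
  } else {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  buffers <- lapply(seq_along(doc$buffers %||% list()), function(i) {
    b <- doc$buffers[[i]]
    if (is.null(b$uri)) glb_bin else decode_uri_or_file(b$uri, dir)
  })

  mat_cache <- new.env()
  read_material <- function(idx) {
    key <- as.character(idx)
    if (!is.null(mat_cache[[key]])) return(mat_cache[[key]])
    m <- if (is.null(idx)) list() else doc$materials[[idx + 1L]]
    pbr <- m$pbrMetallicRoughness %||% list()
    col <- unlist(pbr$baseColorFactor %||% c(1, 1, 1, 1))[1:3]
    tex <- NULL
    if (!is.null(pbr$baseColorTexture)) {
      src <- doc$textures[[pbr$baseColorTexture$index + 1L]]$source
      tex <- gltf_read_image(doc, buffers, dir, src)
    }
    mat_cache[[key]] <- material(pmin(1, pmax(0, col)), tex)
    mat_cache[[key]]
  }

  meshes <- list()
  materials <- list()
  cameras <- list()
  walk <- function(idx, parent) {
    node <- doc$nodes[[idx + 1L]]
    M <- parent %*% gltf_node_matrix(node)
    if (!is.null(node$mesh)) {
      gm <- doc$meshes[[node$mesh + 1L]]
      for (prim in gm$primitives) {
        mode <- prim$mode %||% 4L
        if (mode != 4L)
          stopf("non-triangulable primitive (mode %d) in mesh '%s'",
                mode, gm$name %||% as.character(node$mesh))
        V <- gltf_read_accessor(doc, buffers, prim$attributes$POSITION)
        Vw <- t(M[1:3, 1:3] %*% t(V) + M[1:3, 4])
        tri <- if (!is.null(prim$indices)) {
          matrix(gltf_read_accessor(doc, buffers, prim$indices) + 1L,
                 ncol = 3L, byrow = TRUE)
        } else matrix(seq_len(nrow(V)), ncol = 3L, byrow = TRUE)
        uv <- if (!is.null(prim$attributes$TEXCOORD_0))
          gltf_read_accessor(doc, buffers, prim$attributes$TEXCOORD_0)
        meshes[[length(meshes) + 1L]] <<- triangle_mesh(Vw, tri, uv)
        materials[[length(materials) + 1L]] <<- read_material(prim$material)
      }
    }
    if (!is.null(node$camera)) {
      cam <- doc$cameras[[node$camera + 1L]]
      name <- node$name %||% cam$name %||% sprintf("camera%d", node$camera)
      R3 <- M[1:3, 1:3]
      R3 <- sweep(R3, 2, sqrt(colSums(R3^2)), "/")
      q <- quat_multiply(matrix_to_quat(R3), QUAT_Y180)
      if (q[1] < 0) q <- -q   # canonical sign: q and -q are the same rotation
      pose <- eye_pose(M[1:3, 4], q)
      ex <- cam$extras %||% list()
      if (isTRUE(ex$`compound-eye`)) {
        csv <- ex$`compound-structure`
        if (is.null(csv))
          stopf("compound camera '%s' has no compound-structure eye path", name)
        resolved <- if (grepl("^(/|[A-Za-z]:)", csv)) csv else file.path(dir, csv)
        if (!file.exists(resolved))
          stopf("compound camera '%s' links missing eye file '%s'", name, resolved)
        cameras[[length(cameras) + 1L]] <<-
          camera_spec("compound", pose, name = name, eye_csv = resolved,
                      projection_hint = ex$`compound-projection` %||% "")
      } else if (isTRUE(ex$panoramic)) {
        cameras[[length(cameras) + 1L]] <<- camera_spec("panoramic", pose, name = name)
      } else if (cam$type == "orthographic") {
        cameras[[length(cameras) + 1L]] <<-
          camera_spec("orthographic", pose, name = name,
                      xmag = cam$orthographic$xmag, ymag = cam$orthographic$ymag)
      } else {
        cameras[[length(cameras) + 1L]] <<-
          camera_spec("perspective", pose, name = name,
                      yfov = cam$perspective$yfov)
      }
    }
    for (ch in node$children %||% list()) walk(ch, M)
  }
  sc_idx <- (doc$scene %||% 0L) + 1L
  roots <- if (length(doc$scenes %||% list())) {
    doc$scenes[[sc_idx]]$nodes %||% list()
  } else list()
  for (r in roots) walk(r, diag(4))
  bg <- unlist((doc$scenes[[sc_idx]]$extras %||% list())$background %||% c(1, 1, 1))
  scene(meshes, materials, background = bg[1:3], cameras = cameras)
}
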