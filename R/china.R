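# Packaged constants for the 31 provincial-level units of mainland China
# (Hong Kong, Macao and Taiwan excluded) and their first-order contiguity.

.china_regions_tbl <- local({
  eastern <- c("Beijing", "Tianjin", "Hebei", "Liaoning", "Shanghai",
               "Jiangsu", "Zhejiang", "Fujian", "Shandong", "Guangdong",
               "Hainan")
  central <- c("Shanxi", "Jilin", "Heilongjiang", "Anhui", "Jiangxi",
               "Henan", "Hubei", "Hunan")
  western <- c("Inner Mongolia", "Guangxi", "Chongqing", "Sichuan",
               "Guizhou", "Yunnan", "Tibet", "Shaanxi", "Gansu", "Qinghai",
               "Ningxia", "Xinjiang")
  data.frame(unit = c(eastern, central, western),
             region = rep(c("eastern", "central", "western"),
                          c(length(eastern), length(central), length(western))),
             stringsAsFactors = FALSE)
})

#' The 31 provincial-level units of mainland China
#'
#' @return character vector of 31 province names (eastern, then central, then
#'   western region order).
#' @export
china_provinces <- function() .china_regions_tbl$unit

#' East/central/west regional grouping of the 31 provinces
#'
#' The conventional three-belt economic partition: 11 eastern (coastal),
#' 8 central, 12 western provinces.
#'
#' @return data.frame with columns `unit` and `region`
#'   (`"eastern"`/`"central"`/`"western"`).
#' @export
china_regions <- function() .china_regions_tbl

# First-order (queen) land contiguity between provinces.  Hainan is an island
# with no land border; it is linked to its nearest mainland neighbour
# (Guangdong) so that row-standardization of the weight matrix is defined.
.china_pairs <- local({
  nb <- list(
    Beijing = c("Tianjin", "Hebei"),
    Tianjin = c("Beijing", "Hebei"),
    Hebei = c("Beijing", "Tianjin", "Liaoning", "Inner Mongolia", "Shanxi",
              "Henan", "Shandong"),
    Shanxi = c("Hebei", "Inner Mongolia", "Shaanxi", "Henan"),
    `Inner Mongolia` = c("Heilongjiang", "Jilin", "Liaoning", "Hebei",
                         "Shanxi", "Shaanxi", "Ningxia", "Gansu"),
    Liaoning = c("Jilin", "Inner Mongolia", "Hebei"),
    Jilin = c("Heilongjiang", "Inner Mongolia", "Liaoning"),
    Heilongjiang = c("Inner Mongolia", "Jilin"),
    Shanghai = c("Jiangsu", "Zhejiang"),
    Jiangsu = c("Shandong", "Anhui", "Zhejiang", "Shanghai"),
    Zhejiang = c("Shanghai", "Jiangsu", "Anhui", "Jiangxi", "Fujian"),
    Anhui = c("Jiangsu", "Zhejiang", "Jiangxi", "Hubei", "Henan", "Shandong"),
    Fujian = c("Zhejiang", "Jiangxi", "Guangdong"),
    Jiangxi = c("Zhejiang", "Fujian", "Guangdong", "Hunan", "Hubei", "Anhui"),
    Shandong = c("Hebei", "Henan", "Anhui", "Jiangsu"),
    Henan = c("Hebei", "Shanxi", "Shaanxi", "Hubei", "Anhui", "Shandong"),
    Hubei = c("Henan", "Anhui", "Jiangxi", "Hunan", "Chongqing", "Shaanxi"),
    Hunan = c("Hubei", "Jiangxi", "Guangdong", "Guangxi", "Guizhou",
              "Chongqing"),
    Guangdong = c("Fujian", "Jiangxi", "Hunan", "Guangxi", "Hainan"),
    Guangxi = c("Guangdong", "Hunan", "Guizhou", "Yunnan"),
    Hainan = "Guangdong",
    Chongqing = c("Hubei", "Hunan", "Guizhou", "Sichuan", "Shaanxi"),
    Sichuan = c("Chongqing", "Guizhou", "Yunnan", "Tibet", "Qinghai",
                "Gansu", "Shaanxi"),
    Guizhou = c("Chongqing", "Hunan", "Guangxi", "Yunnan", "Sichuan"),
    Yunnan = c("Guangxi", "Guizhou", "Sichuan", "Tibet"),
    Tibet = c("Yunnan", "Sichuan", "Qinghai", "Xinjiang"),
    Shaanxi = c("Shanxi", "Henan", "Hubei", "Chongqing", "Sichuan", "Gansu",
                "Ningxia", "Inner Mongolia"),
    Gansu = c("Shaanxi", "Sichuan", "Qinghai", "Xinjiang", "Inner Mongolia",
              "Ningxia"),
    Qinghai = c("Gansu", "Sichuan", "Tibet", "Xinjiang"),
    Ningxia = c("Shaanxi", "Gansu", "Inner Mongolia"),
    Xinjiang = c("Gansu", "Qinghai", "Tibet")
  )
  a <- rep(names(nb), lengths(nb))
  b <- unlist(nb, use.names = FALSE)
  keep <- a < b                      # each unordered pair once
  data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
})

#' Contiguity pair list for the 31 Chinese provinces
#'
#' First-order land contiguity; Hainan (an island) is linked to Guangdong so
#' every unit has at least one neighbour and row standardization is defined.
#'
#' @return data.frame with columns `from`, `to`, one row per unordered pair.
#' @export
china_adjacency <- function() .china_pairs
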