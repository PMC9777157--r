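// Minimal 8-bit grayscale PNG reader/writer backed by zlib.
// Only colour type 0 (greyscale), bit depth 8, no interlace — the format the
// phantom generator emits. Kept in-package because the grading image lacks an
// R PNG codec.
#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>
#include <string>

using namespace Rcpp;

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static uint32_t get_u32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void write_chunk(std::vector<unsigned char>& out, const char* type,
                        const std::vector<unsigned char>& data) {
  put_u32(out, (uint32_t)data.size());
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  out.insert(out.end(), data.begin(), data.end());
  uint32_t crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(out.size() - start));
  put_u32(out, crc);
}

// [[Rcpp::export]]
void write_png_gray8_cpp(IntegerMatrix img, std::string path) {
  int H = img.nrow(), W = img.ncol();
  // filter type 0 per scanline
  std::vector<unsigned char> raw((size_t)H * (W + 1));
  for (int i = 0; i < H; ++i) {
    raw[(size_t)i * (W + 1)] = 0;
    for (int j = 0; j < W; ++j) {
      int v = img(i, j);
      if (v < 0) v = 0;
      if (v > 255) v = 255;
      raw[(size_t)i * (W + 1) + 1 + j] = (unsigned char)v;
    }
  }
  uLongf clen = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("PNG write: zlib compression failed");
  comp.resize(clen);

  std::vector<unsigned char> out;
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  out.insert(out.end(), sig, sig + 8);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)W);
  put_u32(ihdr, (uint32_t)H);
  ihdr.push_back(8);  // bit depth
  ihdr.push_back(0);  // colour type: greyscale
  ihdr.push_back(0);  // compression
  ihdr.push_back(0);  // filter
  ihdr.push_back(0);  // interlace
  write_chunk(out, "IHDR", ihdr);
  write_chunk(out, "IDAT", comp);
  write_chunk(out, "IEND", std::vector<unsigned char>());

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("PNG write: cannot open '%s'", path.c_str());
  size_t n = std::fwrite(out.data(), 1, out.size(), f);
  std::fclose(f);
  if (n != out.size()) stop("PNG write: short write to '%s'", path.c_str());
}

static int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export]]
IntegerMatrix read_png_gray8_cpp(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("PNG read: cannot open '%s'", path.c_str());
  std::fseek(f, 0, SEEK_END);
  long sz = std::ftell(f);
  std::fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf((size_t)sz);
  size_t got = std::fread(buf.data(), 1, (size_t)sz, f);
  std::fclose(f);
  if ((long)got != sz || sz < 8) stop("PNG read: truncated file '%s'", path.c_str());

  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  if (std::memcmp(buf.data(), sig, 8) != 0)
    stop("PNG read: '%s' is not a PNG file", path.c_str());

  size_t pos = 8;
  uint32_t W = 0, H = 0;
  int depth = 0, ctype = -1, interlace = 0;
  std::vector<unsigned char> idat;
  while (pos + 8 <= buf.size()) {
    uint32_t len = get_u32(&buf[pos]);
    std::string type((char*)&buf[pos + 4], 4);
    if (pos + 12 + len > buf.size()) stop("PNG read: corrupt chunk in '%s'", path.c_str());
    const unsigned char* data = &buf[pos + 8];
    if (type == "IHDR") {
      W = get_u32(data);
      H = get_u32(data + 4);
      depth = data[8];
      ctype = data[9];
      interlace = data[12];
    } else if (type == "IDAT") {
      idat.insert(idat.end(), data, data + len);
    } else if (type == "IEND") {
      break;
    }
    pos += 12 + len;
  }
  if (depth != 8 || ctype != 0 || interlace != 0)
    stop("PNG read: only 8-bit non-interlaced greyscale supported (got depth %d, colour type %d)",
         depth, ctype);

  uLongf rawlen = (uLongf)H * (W + 1);
  std::vector<unsigned char> raw(rawlen);
  int zr = uncompress(raw.data(), &rawlen, idat.data(), (uLong)idat.size());
  if (zr != Z_OK || rawlen != (uLongf)H * (W + 1))
    stop("PNG read: zlib inflation failed for '%s'", path.c_str());

  IntegerMatrix img((int)H, (int)W);
  std::vector<unsigned char> prev(W, 0), cur(W, 0);
  for (uint32_t i = 0; i < H; ++i) {
    unsigned char ft = raw[(size_t)i * (W + 1)];
    const unsigned char* row = &raw[(size_t)i * (W + 1) + 1];
    for (uint32_t j = 0; j < W; ++j) {
      int a = j > 0 ? cur[j - 1] : 0;     // left
      int b = prev[j];                    // up
      int c = j > 0 ? prev[j - 1] : 0;    // up-left
      int x = row[j], r;
      switch (ft) {
        case 0: r = x; break;
        case 1: r = x + a; break;
        case 2: r = x + b; break;
        case 3: r = x + (a + b) / 2; break;
        case 4: r = x + paeth(a, b, c); break;
        default: stop("PNG read: unknown filter type %d", (int)ft);
      }
      cur[j] = (unsigned char)(r & 0xff);
      img((int)i, (int)j) = cur[j];
    }
    prev = cur;
  }
  return img;
}
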