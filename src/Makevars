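PKG_CPPFLAGS = -DARMA_USE_FFTW3
PKG_LIBS = -lfftw3
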