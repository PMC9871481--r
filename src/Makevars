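PKG_CPPFLAGS = -I$(R_HOME)/../../include
PKG_LIBS = -L$(R_HOME)/../../lib -lhdf5 $(BLAS_LIBS) $(FLIBS)
PKG_CXXFLAGS = -O3 -funroll-loops
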