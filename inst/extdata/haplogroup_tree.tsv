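root		
L0d2c	root	A1000G,C2000T,G3000A
L0d2c1	L0d2c	T4000C,A5000G
L0d2c1a	L0d2c1	C6000T,A7000G
L0d2c1b	L0d2c1	G8000A,T9000C
L0d2c1c	L0d2c1	C10822A,C16355T
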