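>synthetic_lpmo10c synthetic modular LPMO-like parent
TTSFANLFYSYLFLGVTWAFFSALFGLWVFNNWGGGWFGVWFYSNTVSTNFNSFWNSALV
VANAGAVNVFFNWYLALYLTSAYLNYGFWWAGANSNSNGVVWVWFAFAGFGFYWNGLSVW
SYTWWGWTWNNNAAASALWWNGLSSVYGNYGLFGVNAGYGLSYFYTATVNTWNSSVLWGF
NVNTLTGWGWFLGSGLLGFSAGVLWVYTGWSNWATYANGGVGGYSNLFTPGPSTDGTPKT
PENGTSGTPDSTPGNGEPTSGPTSNYGVTGNVFNGATWTSATWAYTNSWWYLAGTTVTWF
FSFAVSGLWLWFYGNTLAYLSLFLGFAVVVAGATVNNGNNAGGLLGLLAFNVGYSYSGTW
LFYA
>synthetic_modular_2 synthetic two-domain parent
TFGSNTWGYGVLATLGLTYGFTLGWSFNAGFNSFYFTNWFLFVTWTFVSWGATVAVNGSF
WTANGNWNWFTGVFSWWVTTGYYVNFVVWWFNYGALGNSYYVVTLGNWFTVSNNWYNGLN
TGFFYNLVNTAVFVSTWVYYAVASAAVWNFYLSNAYWYVNTTWVVTWNTAGLFTVNAFVT
GSETQVGVATGGDTGPPPGTSPTEGDVNFSLTLWATSGVAWFFYNVYLLSNNYLGNFTAN
WVYFYWVTAFLYFNVGGFLAYAGFYSVSNTWSAWGSWLFVYSYFWTFNWGGWNYLW
>synthetic_modular_3 synthetic two-domain parent
NGNFAVGFFSALFGSVLVLFWFVYYAWVAATSWWFYNNLLFWGSVNVGGGNTYNNTYNAG
WSWWVATFNGYVYWTNYWGYSVYAWLLVGLWALWTTSGNATLVNAAVGLAAYGYNFGWAY
VSYVFYFTFLSANWSVTYLGWWAYTAYLGTGGTVETSGTTEPTTQGGSVPTGAGPTSGAG
TGSAAGNAPTQPATDDPTAQDGVGAGTTLNVFYNVAGYNAFLTFTLWFTFYWVGFAASVW
SNLSAALYVGTALWGWFTSYSSNLWLSFYFVLGAANGTSFVTVTWVNGWWAWLTYWNLVS
LGVYVTGYAGAWVTWYGT
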