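>synthAlb1_1 synthetic albumin-1-like mature chain
VGAMFWVSICFGRWSECLFGQGCDKECAMNSKFFWQGCFDWECVWHHDE
>synthAlb1_2 synthetic albumin-1-like mature chain
DHMKGAVIFQCMLPLNETCGRGDWCVWGCRKKFFIMWQYCTVPLCNTKHA
>synthAlb1_3 synthetic albumin-1-like mature chain
QRGLTNMMCAYVRRSCHSNGTCVVWCDHHHSDMPLADCDNRDCDMGMVV
>synthAlb1_4 synthetic albumin-1-like mature chain
GERRAGEQNCVFNVLVCQVAVCADKCTEGQPAYGSHCTMILCLEWSS
>synthAlb1_5 synthetic albumin-1-like mature chain
TAHNLQGNSDCHARTVNCWDMFSCIVGCWLNHMLYLNYCFMVPHCSLMWIR
>synthAlb1_6 synthetic albumin-1-like mature chain
PYMGDEDRCTFHNARCAFQHPCIPGCWIQDEASNLCMIYWCPMLYS
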