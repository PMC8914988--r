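activity,label,blob,center_row,center_col,row_spread,col_spread,amplitude
act01,stand,1,12.5,3.0,2.2,1.2,900
act02,fold_arms,1,7.0,2.5,1.8,1.3,2200
act02,fold_arms,2,9.5,4.8,1.5,0.9,1800
act03,think,1,15.5,3.5,0.9,1.1,3000
act03,think,2,10.0,2.0,1.4,0.9,1200
act04,side_against_wall,1,9.0,1.2,3.8,0.8,2000
act05,back_against_wall,1,8.0,5.2,3.8,0.8,2000
act06,arm_on_baffle,1,12.0,3.5,1.2,1.6,2600
act07,hug_doll,1,6.0,3.0,2.8,1.6,1500
act07,hug_doll,2,12.5,4.5,1.6,1.0,1400
act08,carry_box,1,4.5,2.5,1.6,1.2,2800
act08,carry_box,2,14.0,4.5,1.5,1.0,2400
act09,lean_forward_work,1,12.5,3.5,2.4,1.6,2000
act10,lean_back_work,1,16.0,3.5,0.7,1.0,1500
act11,sleep_on_table,1,5.5,3.5,2.4,1.8,3200
act12,hold_cheeks,1,15.8,2.2,0.8,0.8,3100
act13,play_phone,1,10.0,4.8,2.0,1.0,1100
act14,write_hunchback,1,13.0,2.8,2.0,1.4,2300
act14,write_hunchback,2,8.0,4.5,1.0,0.8,800
act15,write_straight,1,13.5,4.2,1.8,1.1,2100
act16,hands_on_armrests,1,11.5,1.5,1.4,0.9,1900
act16,hands_on_armrests,2,11.5,5.2,1.4,0.9,1900
act17,sit_leaning_right,1,9.5,5.5,2.2,0.8,2200
act18,arms_on_legs,1,10.5,3.2,1.6,1.8,1700
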